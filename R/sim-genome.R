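#' Generate a human-like / mouse-like reference pair
#'
#' Builds a small two-chromosome reference ("autosome" and "chrX", uppercase
#' ACGT) and a second reference derived from it by independent per-base
#' substitution at rate `config$divergence`. The pair stands in for the two
#' genomes of a xenograft experiment: reads from the second genome are the
#' "mouse" contamination the deconvolution step must remove.
#'
#' @param config A [sim_config()].
#' @return A list with elements `human` and `mouse`, each a
#'   [Biostrings::DNAStringSet] with records `autosome` and `chrX`.
#' @export
#' @examples
#' refs <- sim_reference_pair(sim_config(seed = 1, genome_length = 2000))
#' Biostrings::width(refs$human)
sim_reference_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length < config$read_length) {
    stop("sequence length must be at least the read length", call. = FALSE)
  }
  withr::with_seed(sub_seed(config, 11L), {
    bases <- c("A", "C", "G", "T")
    n_auto <- ceiling(config$genome_length * 0.75)
    n_x <- config$genome_length - n_auto
    if (n_x < config$read_length) { # keep both chromosomes readable
      n_x <- min(config$read_length, config$genome_length %/% 2)
      n_auto <- config$genome_length - n_x
    }
    human <- c(
      autosome = paste(sample(bases, n_auto, replace = TRUE), collapse = ""),
      chrX = paste(sample(bases, n_x, replace = TRUE), collapse = "")
    )
    mouse <- vapply(human, function(seq) {
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      hit <- stats::runif(length(ch)) < config$divergence
      if (any(hit)) {
        # substitute with a uniformly chosen different base, so divergence 1
        # forces every position to change
        ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(bases, b), 1), "")
      }
      paste(ch, collapse = "")
    }, "")
    list(
      human = Biostrings::DNAStringSet(human),
      mouse = Biostrings::DNAStringSet(mouse)
    )
  })
}

#' Simulate a labeled xenograft read set
#'
#' Draws `n_reads` error-free reads of length `config$read_length` from
#' uniformly random positions and strands, taking each read from the mouse
#' reference with probability `config$contamination` and from the human
#' reference otherwise. The true origin of each read is recorded so that
#' classifier accuracy can be measured against ground truth.
#'
#' @param config A [sim_config()].
#' @param references Reference pair from [sim_reference_pair()].
#' @param n_reads Number of reads to draw.
#' @return A tibble with columns `read_id`, `sequence`, `origin`
#'   (`"human"` or `"mouse"`).
#' @export
sim_reads <- function(config, references, n_reads = 5000L) {
  stopifnot(inherits(config, "sim_config"))
  rl <- config$read_length
  widths <- Biostrings::width(references$human)
  if (any(rl > widths)) {
    stop("read length exceeds a reference chromosome length", call. = FALSE)
  }
  withr::with_seed(sub_seed(config, 23L), {
    origin <- ifelse(stats::runif(n_reads) < config$contamination,
                     "mouse", "human")
    chroms <- names(references$human)
    # chromosomes sampled proportionally to length
    chrom <- sample(chroms, n_reads, replace = TRUE,
                    prob = widths / sum(widths))
    seqs <- character(n_reads)
    for (org in c("human", "mouse")) {
      ref <- as.character(references[[org]])
      idx <- which(origin == org)
      if (!length(idx)) next
      starts <- vapply(chrom[idx], function(cn) {
        sample.int(nchar(ref[[cn]]) - rl + 1L, 1L)
      }, integer(1))
      raw <- substring(ref[chrom[idx]], starts, starts + rl - 1L)
      flip <- stats::runif(length(idx)) < 0.5
      raw[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(raw[flip]))
      )
      seqs[idx] <- raw
    }
    tibble::tibble(
      read_id = sprintf("read_%05d", seq_len(n_reads)),
      sequence = seqs,
      origin = origin
    )
  })
}

#' Simulate gene models over the synthetic genome
#'
#' Lays out `config$n_genes` non-overlapping genes along the two synthetic
#' chromosomes, roughly one gene in eight on chrX, each with 1-3 exons and a
#' total exon length drawn between 500 and 3000 bp. Coordinates are 0-based
#' half-open (BED convention) and are only nominal: the coverage simulator
#' uses exon lengths, not sequence.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`
#'   (one row per exon).
#' @export
sim_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config, 31L), {
    n <- config$n_genes
    chromosome <- ifelse(seq_len(n) %% 8L == 0L, "chrX", "autosome")
    rows <- vector("list", n)
    cursor <- c(autosome = 0L, chrX = 0L)
    for (i in seq_len(n)) {
      n_exon <- sample(1:3, 1)
      total <- sample(500:3000, 1)
      cuts <- sort(sample.int(total - 1L, n_exon - 1L))
      lens <- diff(c(0L, cuts, total))
      chrom <- chromosome[i]
      starts <- integer(n_exon)
      ends <- integer(n_exon)
      pos <- cursor[[chrom]]
      for (j in seq_len(n_exon)) {
        starts[j] <- pos
        ends[j] <- pos + lens[j]
        pos <- ends[j] + sample(50:200, 1) # intron / intergenic gap
      }
      cursor[[chrom]] <- pos
      rows[[i]] <- tibble::tibble(
        gene_id = sprintf("gene_%03d", i),
        chromosome = chrom, start = starts, end = ends
      )
    }
    dplyr::bind_rows(rows)
  })
}
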