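#' Build a canonical k-mer index of a reference
#'
#' Collects every k-mer of the reference (all records pooled), keyed by its
#' canonical form: the lexicographic minimum of the k-mer and its reverse
#' complement, so lookups are strand-insensitive. Windows containing
#' non-ACGT characters are skipped; their count is kept in the
#' `n_skipped` attribute.
#'
#' @param reference A [Biostrings::DNAStringSet], `DNAString`, or character
#'   vector of sequences.
#' @param k k-mer size (>= 1).
#' @return Character vector of unique canonical k-mers, with attributes
#'   `k` and `n_skipped`.
#' @export
#' @examples
#' kmer_index("ACGTACGT", k = 4)
kmer_index <- function(reference, k = 15L) {
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  seqs <- as.character(reference)
  if (all(nchar(seqs) < k)) {
    stop("reference shorter than k", call. = FALSE)
  }
  kmers <- character(0)
  n_skipped <- 0L
  for (s in seqs) {
    L <- nchar(s)
    if (L < k) next
    win <- substring(s, seq_len(L - k + 1L), k:L)
    ok <- !grepl("[^ACGT]", win)
    n_skipped <- n_skipped + sum(!ok)
    kmers <- c(kmers, win[ok])
  }
  kmers <- unique(kmers)
  canon <- canonical_kmers(kmers)
  structure(unique(canon), k = as.integer(k), n_skipped = n_skipped)
}

canonical_kmers <- function(kmers) {
  if (!length(kmers)) return(character(0))
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(kmers))
  )
  pmin(kmers, rc)
}

#' Classify reads as human- or mouse-origin by k-mer containment
#'
#' Scores each read by the number of its canonical k-mers present in the
#' human and in the mouse index. A read is called `human` if
#' `human_score >= mouse_score + margin`, `mouse` if
#' `mouse_score >= human_score + margin`, and `ambiguous` otherwise
#' (including reads shorter than k, which score 0 against both). This
#' containment rule stands in for the conventional two-genome alignment
#' filter used to deconvolve xenograft sequencing data.
#'
#' @param reads Tibble with `read_id` and `sequence` columns (as from
#'   [sim_reads()]), or a character vector of sequences.
#' @param human_index,mouse_index Indexes from [kmer_index()], built with
#'   the same k.
#' @param margin Minimum score lead required for a non-ambiguous call.
#' @return Tibble with `read_id`, `human_score`, `mouse_score`, `call`.
#' @export
classify_reads <- function(reads, human_index, mouse_index, margin = 1L) {
  k <- attr(human_index, "k")
  if (!identical(k, attr(mouse_index, "k"))) {
    stop("indexes were built with different k", call. = FALSE)
  }
  if (margin < 0) stop("`margin` must be >= 0", call. = FALSE)
  if (is.character(reads)) {
    reads <- tibble::tibble(
      read_id = sprintf("read_%05d", seq_along(reads)), sequence = reads
    )
  }
  # flatten all read windows into one batch so the reverse complement and
  # membership tests run once over the whole read set
  n <- nrow(reads)
  L <- nchar(reads$sequence)
  n_win <- pmax(L - k + 1L, 0L)
  hs <- integer(n)
  ms <- integer(n)
  has_win <- which(n_win > 0L)
  if (length(has_win)) {
    owner <- rep.int(has_win, n_win[has_win])
    starts <- unlist(lapply(n_win[has_win], seq_len), use.names = FALSE)
    win <- substring(reads$sequence[owner], starts, starts + k - 1L)
    ok <- !grepl("[^ACGT]", win)
    owner <- owner[ok]
    win <- canonical_kmers(win[ok])
    hs_hit <- win %in% human_index
    ms_hit <- win %in% mouse_index
    if (length(owner)) {
      hs_tab <- rowsum(as.integer(hs_hit), owner)
      ms_tab <- rowsum(as.integer(ms_hit), owner)
      idx <- as.integer(rownames(hs_tab))
      hs[idx] <- hs_tab[, 1]
      ms[idx] <- ms_tab[, 1]
    }
  }
  call <- dplyr::case_when(
    hs >= ms + margin ~ "human",
    ms >= hs + margin ~ "mouse",
    TRUE ~ "ambiguous"
  )
  tibble::tibble(
    read_id = reads$read_id,
    human_score = hs, mouse_score = ms, call = call
  )
}

#' Partition a read set into human, mouse and ambiguous subsets
#'
#' Classifies every read with [classify_reads()] and splits the input into
#' three disjoint subsets whose sizes sum to the input size. Ambiguous
#' reads (no score lead of at least `margin` either way) are set aside
#' rather than silently assigned; downstream counting should use the
#' `human` subset only.
#'
#' @param reads Read tibble (`read_id`, `sequence`, other columns carried
#'   through).
#' @param human_ref,mouse_ref References (anything [kmer_index()] accepts).
#' @param k k-mer size.
#' @param margin Call margin, see [classify_reads()].
#' @return A list with tibbles `human`, `mouse`, `ambiguous`, and `summary`
#'   (one row per call class with `n` and `fraction`).
#' @export
partition_reads <- function(reads, human_ref, mouse_ref, k = 15L, margin = 1L) {
  hidx <- kmer_index(human_ref, k)
  midx <- kmer_index(mouse_ref, k)
  n <- nrow(reads)
  if (n == 0) {
    empty <- reads
    summary <- tibble::tibble(
      call = c("human", "mouse", "ambiguous"), n = 0L, fraction = NA_real_
    )
    return(list(human = empty, mouse = empty, ambiguous = empty,
                summary = summary))
  }
  cls <- classify_reads(reads, hidx, midx, margin)
  out <- lapply(c(human = "human", mouse = "mouse", ambiguous = "ambiguous"),
                function(cc) reads[cls$call == cc, , drop = FALSE])
  summary <- dplyr::count(cls, call = factor(call, c("human", "mouse", "ambiguous")),
                          .drop = FALSE, name = "n")
  summary$call <- as.character(summary$call)
  summary$fraction <- summary$n / n
  c(out, list(summary = summary))
}
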