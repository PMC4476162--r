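#' Create a named hexamer motif set
#'
#' @param motifs Character vector of 6-nt motifs over A/C/G/T; duplicates
#'   are dropped.
#' @param name Label for the set (e.g. `"INT3"`).
#' @return An object of class `hexamer_set`: a character vector with a
#'   `name` attribute.
#' @export
hexamer_set <- function(motifs, name = "ESE") {
  motifs <- unique(toupper(motifs))
  check_that(length(motifs) > 0, "motif set is empty")
  check_that(all(nchar(motifs) == 6L), "all motifs must be 6 nt long")
  check_that(all(grepl("^[ACGT]{6}$", motifs)),
             "motifs must use the A/C/G/T alphabet only")
  structure(motifs, name = name, class = c("hexamer_set", "character"))
}

#' @export
print.hexamer_set <- function(x, ...) {
  cat("<hexamer_set> ", attr(x, "name"), ": ", length(x), " motifs\n", sep = "")
  invisible(x)
}

#' Read a hexamer set from a plain-text file (one 6-mer per line)
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param name Set label; defaults to the file name without extension.
#' @return A [hexamer_set()].
#' @export
read_hexamer_set <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  hexamer_set(lines, name = name)
}

#' Pooled nucleotide composition of a hexamer set
#'
#' @param motifs A [hexamer_set()] or character vector of hexamers.
#' @return Named numeric vector of A/C/G/T frequencies (sums to 1).
#' @export
hexamer_base_freqs <- function(motifs) {
  chars <- strsplit(paste(motifs, collapse = ""), "")[[1]]
  tab <- table(factor(chars, levels = BASES))
  as.vector(tab / sum(tab)) |> setNames(BASES)
}

#' Draw pseudo-ESE hexamer sets matched in size and nucleotide content
#'
#' Each replicate set contains the same number of unique hexamers as the
#' true set, with positions drawn i.i.d. from the true set's pooled base
#' frequencies (duplicates within a set are redrawn). Exact matches to the
#' true motifs are not excluded: the sets are matched in average
#' composition only, serving as a mutational/nucleotide-bias null.
#'
#' @param motifs A [hexamer_set()].
#' @param n_sets Number of replicate sets.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return A list of [hexamer_set()] objects named `pseudo_1`, ...
#' @export
pseudo_ese_sets <- function(motifs, n_sets = 100, seed = 1L) {
  freqs <- hexamer_base_freqs(motifs)
  k <- length(motifs)
  set.seed(seed)
  lapply(seq_len(n_sets), function(i) {
    out <- character(0)
    tries <- 0L
    while (length(out) < k) {
      need <- k - length(out)
      draw <- matrix(sample(BASES, 6L * need, replace = TRUE, prob = freqs),
                     nrow = need)
      out <- unique(c(out, apply(draw, 1L, paste, collapse = "")))
      tries <- tries + 1L
      check_that(tries < 1000L, "could not draw enough unique hexamers")
    }
    hexamer_set(out[seq_len(k)], name = paste0("pseudo_", i))
  })
}

#' Per-nucleotide ESE coverage of flank sequences
#'
#' Marks every position covered by at least one exact hexamer match
#' (overlapping hits are unioned).
#'
#' @param seqs Character vector of equal-length sequences (A/C/G/T only).
#' @param motifs A [hexamer_set()].
#' @return Logical matrix `length(seqs) x width`; `TRUE` where covered.
#' @export
ese_coverage <- function(seqs, motifs) {
  check_that(length(seqs) > 0, "no sequences given")
  w <- unique(nchar(seqs))
  check_that(length(w) == 1L, "sequences must have equal length")
  check_that(w >= 6L, "sequences must be at least 6 nt")
  check_that(!any(grepl("[^ACGT]", seqs)),
             "sequences contain non-ACGT characters; filter upstream")
  n <- length(seqs)
  n_win <- w - 5L
  starts <- seq_len(n_win)
  # windows: n x n_win matrix of 6-mers
  win <- matrix(substring(rep(seqs, each = n_win), starts, starts + 5L),
                nrow = n, ncol = n_win, byrow = TRUE)
  hits <- matrix(win %in% motifs, nrow = n, ncol = n_win)
  cov <- matrix(FALSE, n, w)
  for (k in 0:5) {
    idx <- starts + k
    cov[, idx] <- cov[, idx] | hits
  }
  cov
}

#' ESE mask and density of a single flank sequence
#'
#' @param flank_seq A 69-nt (or other length >= 6) A/C/G/T string.
#' @param motifs A [hexamer_set()].
#' @return A one-row tibble with `density` (covered fraction), `n_covered`,
#'   `width`, and a list-column `covered_sites` of 0-based covered
#'   positions.
#' @examples
#' mask_ese(strrep("GAAGAAGAA", 8) |> substr(1, 69), hexamer_set("GAAGAA"))
#' @export
mask_ese <- function(flank_seq, motifs) {
  cov <- ese_coverage(flank_seq, motifs)[1, ]
  tibble(density = mean(cov), n_covered = sum(cov), width = length(cov),
         covered_sites = list(which(cov) - 1L))
}

#' ESE density of many flank sequences
#'
#' @inheritParams ese_coverage
#' @return Numeric vector of covered fractions, one per sequence.
#' @export
ese_density <- function(seqs, motifs) {
  rowMeans(ese_coverage(seqs, motifs))
}
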