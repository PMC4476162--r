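# Standard genetic code, codon indexing and NG86 lookup tables.
#
# Codons are indexed 1..64 in lexicographic order over the alphabet
# A < C < G < T (i.e. AAA = 1, TTT = 64). All NG86 quantities are
# precomputed once per session into lookup tables so that Ks on long
# concatenations reduces to indexed sums.

BASES <- c("A", "C", "G", "T")

#' All 64 codons in lexicographic (A,C,G,T) order
#' @keywords internal
#' @noRd
all_codons <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Standard genetic code as a named vector codon -> one-letter amino acid
#' ("*" for stop)
#' @keywords internal
#' @noRd
genetic_code <- function() {
  aa <- c(
    "AAA" = "K", "AAC" = "N", "AAG" = "K", "AAT" = "N",
    "ACA" = "T", "ACC" = "T", "ACG" = "T", "ACT" = "T",
    "AGA" = "R", "AGC" = "S", "AGG" = "R", "AGT" = "S",
    "ATA" = "I", "ATC" = "I", "ATG" = "M", "ATT" = "I",
    "CAA" = "Q", "CAC" = "H", "CAG" = "Q", "CAT" = "H",
    "CCA" = "P", "CCC" = "P", "CCG" = "P", "CCT" = "P",
    "CGA" = "R", "CGC" = "R", "CGG" = "R", "CGT" = "R",
    "CTA" = "L", "CTC" = "L", "CTG" = "L", "CTT" = "L",
    "GAA" = "E", "GAC" = "D", "GAG" = "E", "GAT" = "D",
    "GCA" = "A", "GCC" = "A", "GCG" = "A", "GCT" = "A",
    "GGA" = "G", "GGC" = "G", "GGG" = "G", "GGT" = "G",
    "GTA" = "V", "GTC" = "V", "GTG" = "V", "GTT" = "V",
    "TAA" = "*", "TAC" = "Y", "TAG" = "*", "TAT" = "Y",
    "TCA" = "S", "TCC" = "S", "TCG" = "S", "TCT" = "S",
    "TGA" = "*", "TGC" = "C", "TGG" = "W", "TGT" = "C",
    "TTA" = "L", "TTC" = "F", "TTG" = "L", "TTT" = "F"
  )
  aa[all_codons()]
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(all_codons(), STOP_CODONS)

#' Translate a codon character vector to amino acids
#' @keywords internal
#' @noRd
translate_codons <- function(codons) {
  unname(genetic_code()[codons])
}

#' Split an in-frame nucleotide string into codons
#' @keywords internal
#' @noRd
codons_of <- function(seq) {
  n <- nchar(seq)
  check_that(n %% 3 == 0, "sequence length must be a multiple of 3")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Map codon strings to 1..64 indices (NA for anything non-ACGT)
#' @keywords internal
#' @noRd
codon_index <- function(codons) {
  match(codons, all_codons())
}

# -- NG86 per-codon and per-codon-pair tables ---------------------------------

# cache environment for lazily built tables
.ng86_cache <- new.env(parent = emptyenv())

#' Synonymous site count of each codon (NG86 convention)
#'
#' For each of the three positions the fraction of the three possible single
#' nucleotide changes that are synonymous; changes to stop codons count as
#' nonsynonymous; stop codons themselves get NA.
#' @keywords internal
#' @noRd
ng86_syn_sites <- function() {
  if (!is.null(.ng86_cache$syn_sites)) return(.ng86_cache$syn_sites)
  code <- genetic_code()
  codons <- all_codons()
  s <- vapply(codons, function(cd) {
    if (code[[cd]] == "*") return(NA_real_)
    tot <- 0
    for (pos in 1:3) {
      b <- substr(cd, pos, pos)
      alts <- setdiff(BASES, b)
      syn <- 0L
      for (a in alts) {
        mut <- cd
        substr(mut, pos, pos) <- a
        if (code[[mut]] != "*" && code[[mut]] == code[[cd]]) syn <- syn + 1L
      }
      tot <- tot + syn / 3
    }
    tot
  }, numeric(1))
  .ng86_cache$syn_sites <- unname(s)
  .ng86_cache$syn_sites
}

#' NG86 synonymous/nonsynonymous difference counts for every codon pair
#'
#' Returns a list of two 64 x 64 matrices (`sd`, `nd`): expected synonymous
#' and nonsynonymous differences between codon i and codon j, averaging over
#' all minimal mutational pathways that do not pass through a stop codon.
#' Pairs involving a stop codon, or whose every pathway passes through a
#' stop, are NA.
#' @keywords internal
#' @noRd
ng86_pair_diffs <- function() {
  if (!is.null(.ng86_cache$pair)) return(.ng86_cache$pair)
  code <- genetic_code()
  codons <- all_codons()
  n <- length(codons)
  sd_m <- matrix(0, n, n, dimnames = list(codons, codons))
  nd_m <- matrix(0, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i) next
      a <- codons[i]; b <- codons[j]
      if (code[[a]] == "*" || code[[b]] == "*") {
        sd_m[i, j] <- sd_m[j, i] <- NA_real_
        nd_m[i, j] <- nd_m[j, i] <- NA_real_
        next
      }
      d <- ng86_path_average(a, b, code)
      sd_m[i, j] <- sd_m[j, i] <- d[["sd"]]
      nd_m[i, j] <- nd_m[j, i] <- d[["nd"]]
    }
  }
  .ng86_cache$pair <- list(sd = sd_m, nd = nd_m)
  .ng86_cache$pair
}

#' Average syn/nonsyn differences between two codons over minimal pathways
#' @keywords internal
#' @noRd
ng86_path_average <- function(a, b, code = genetic_code()) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations_of(pos)
  sd_tot <- 0; nd_tot <- 0; n_ok <- 0L
  for (p in seq_len(nrow(perms))) {
    cur <- a
    sd_p <- 0; nd_p <- 0; ok <- TRUE
    for (step in perms[p, ]) {
      nxt <- cur
      substr(nxt, step, step) <- substr(b, step, step)
      if (code[[nxt]] == "*") { ok <- FALSE; break }
      if (code[[nxt]] == code[[cur]]) sd_p <- sd_p + 1 else nd_p <- nd_p + 1
      cur <- nxt
    }
    if (ok) { sd_tot <- sd_tot + sd_p; nd_tot <- nd_tot + nd_p; n_ok <- n_ok + 1L }
  }
  if (n_ok == 0L) return(c(sd = NA_real_, nd = NA_real_))
  c(sd = sd_tot / n_ok, nd = nd_tot / n_ok)
}

#' All permutations of a small vector (n <= 3 here)
#' @keywords internal
#' @noRd
permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1, 1))
  if (n == 2L) return(rbind(x, rev(x)))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  unname(out)
}

#' Synonymous third-position neighbours of each codon
#'
#' List indexed by codon (1..64): the codons that differ only at the third
#' position and encode the same amino acid (never a stop). Used by the
#' ortholog simulator.
#' @keywords internal
#' @noRd
syn3_neighbours <- function() {
  if (!is.null(.ng86_cache$syn3)) return(.ng86_cache$syn3)
  code <- genetic_code()
  codons <- all_codons()
  out <- lapply(codons, function(cd) {
    if (code[[cd]] == "*") return(character(0))
    alts <- vapply(setdiff(BASES, substr(cd, 3, 3)), function(a) {
      mut <- cd
      substr(mut, 3, 3) <- a
      mut
    }, character(1))
    alts[code[alts] == code[[cd]]]
  })
  names(out) <- codons
  .ng86_cache$syn3 <- out
  out
}
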