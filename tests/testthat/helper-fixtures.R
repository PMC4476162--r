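# Shared fixtures, built in code and cached per test session.

fixture_env <- new.env(parent = emptyenv())

# small simulated species with features (used across modules)
small_species <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- sim_config(seed = 42L, n_genes = 80L)
    sim <- simulate_species_genes(cfg)
    fixture_env$small <- list(
      cfg = cfg, sim = sim,
      features = extract_internal_exon_features(sim$genes)
    )
  }
  fixture_env$small
}

# brute-force NG86 oracle: direct path enumeration written independently
# of the lookup-table implementation
oracle_ng86 <- function(seq_a, seq_b) {
  code <- splicesel:::genetic_code()
  stops <- names(code)[code == "*"]
  split_codons <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  syn_sites_codon <- function(cd) {
    if (code[[cd]] == "*") return(NA_real_)
    tot <- 0
    for (pos in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(cd, pos, pos))) {
        mut <- cd; substr(mut, pos, pos) <- b
        if (!mut %in% stops && code[[mut]] == code[[cd]]) tot <- tot + 1 / 3
      }
    }
    tot
  }
  path_diffs <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (length(pos) == 0) return(c(0, 0))
    perms <- if (length(pos) == 1) list(pos) else {
      # all orderings
      do.call(c, lapply(seq_along(pos), function(i) {
        rest <- pos[-i]
        if (length(rest) == 1) list(c(pos[i], rest)) else
          lapply(list(rest, rev(rest)), function(r) c(pos[i], r))
      }))
    }
    tot_s <- 0; tot_n <- 0; ok <- 0
    for (p in perms) {
      cur <- a; s <- 0; n <- 0; valid <- TRUE
      for (step in p) {
        nxt <- cur; substr(nxt, step, step) <- substr(b, step, step)
        if (nxt %in% stops) { valid <- FALSE; break }
        if (code[[nxt]] == code[[cur]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n; ok <- ok + 1 }
    }
    if (ok == 0) return(c(NA_real_, NA_real_))
    c(tot_s / ok, tot_n / ok)
  }
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  ss <- 0; sdf <- 0
  for (i in seq_along(ca)) {
    if (ca[i] %in% stops || cb[i] %in% stops) next
    d <- path_diffs(ca[i], cb[i])
    if (is.na(d[1])) next
    ss <- ss + (syn_sites_codon(ca[i]) + syn_sites_codon(cb[i])) / 2
    sdf <- sdf + d[1]
  }
  ps <- sdf / ss
  ks <- if (ps >= 3 / 4) NA_real_ else -(3 / 4) * log(1 - (4 / 3) * ps)
  list(ps = ps, ks = ks, syn_sites = ss, syn_diffs = sdf)
}

random_codon_seq <- function(n_codons) {
  paste(sample(splicesel:::SENSE_CODONS, n_codons, replace = TRUE),
        collapse = "")
}

# one-sided binomial check that an observed rate is compatible with a
# stated upper bound (used for stochastic size/error-rate assertions)
rate_not_above <- function(n_hits, n_trials, bound) {
  stats::binom.test(n_hits, n_trials, p = min(bound, 1),
                    alternative = "greater")$p.value > 0.05
}
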