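# Independent oracles used to verify the package's estimators. They are
# written against Biostrings::GENETIC_CODE (the package hard-codes its own
# table) and use straightforward enumeration rather than the implementation's
# vectorized/cached paths.

oracle_code <- function() Biostrings::GENETIC_CODE

oracle_sense_codons <- function() {
  gc <- oracle_code()
  names(gc)[gc != "*"]
}

# NG86 synonymous site count of one codon, stop neighbours excluded from
# numerator and denominator at each position.
oracle_syn_sites <- function(codon) {
  gc <- oracle_code()
  aa <- gc[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0L
    ok <- 0L
    for (base in c("A", "C", "G", "T")) {
      if (base == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- base
      if (gc[[mut]] == "*") next
      ok <- ok + 1L
      if (gc[[mut]] == aa) syn <- syn + 1L
    }
    if (ok > 0L) total <- total + syn / ok
  }
  total
}

oracle_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# Pathway-averaged synonymous/nonsynonymous differences for one codon pair,
# pathways through stop codons excluded; single-position fallback when all
# pathways are blocked.
oracle_diffs <- function(ca, cb) {
  gc <- oracle_code()
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(pos) == 0L) return(c(0, 0))
  acc <- NULL
  for (ord in oracle_permutations(pos)) {
    cur <- ca
    steps <- c(0, 0)
    valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*") {
        valid <- FALSE
        break
      }
      if (gc[[nxt]] == gc[[cur]]) steps[1] <- steps[1] + 1
      else steps[2] <- steps[2] + 1
      cur <- nxt
    }
    if (valid) acc <- rbind(acc, steps)
  }
  if (is.null(acc)) {
    steps <- c(0, 0)
    for (p in pos) {
      nxt <- ca
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] != "*" && gc[[nxt]] == gc[[ca]]) {
        steps[1] <- steps[1] + 1
      } else {
        steps[2] <- steps[2] + 1
      }
    }
    return(steps)
  }
  colMeans(acc)
}

# Full NG86 Ka/Ks from two equal-length sense-codon vectors.
oracle_kaks <- function(codons_a, codons_b) {
  stopifnot(length(codons_a) == length(codons_b))
  s_sites <- (sum(vapply(codons_a, oracle_syn_sites, 0)) +
                sum(vapply(codons_b, oracle_syn_sites, 0))) / 2
  n_sites <- 3 * length(codons_a) - s_sites
  sd <- 0
  nd <- 0
  for (i in seq_along(codons_a)) {
    d <- oracle_diffs(codons_a[i], codons_b[i])
    sd <- sd + d[1]
    nd <- nd + d[2]
  }
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 / 3 * p) else NA_real_
  c(ka = jc(nd / n_sites), ks = jc(sd / s_sites), sd = sd, nd = nd,
    s_sites = s_sites, n_sites = n_sites)
}

# Brute-force global alignment score: enumerate every monotone matching of
# residues (= every alignment up to gap interleaving) and score it with
# BLOSUM62 substitution scores minus affine gap costs (a run of length L
# costs open + ext * L); unmatched residues between two consecutive matches
# form one run per sequence, which is the gap-cost-minimal interleaving.
oracle_align_score <- function(a, b, open = 10, ext = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  M <- env$BLOSUM62
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  la <- length(av)
  lb <- length(bv)
  run_cost <- function(runs) -sum(ifelse(runs > 0, open + ext * runs, 0))
  best <- run_cost(la) + run_cost(lb)  # the empty matching
  for (k in seq_len(min(la, lb))) {
    SA <- utils::combn(la, k)
    SB <- utils::combn(lb, k)
    ga <- apply(SA, 2, function(s) {
      run_cost(c(s[1] - 1, diff(s) - 1, la - s[k]))
    })
    gb <- apply(SB, 2, function(s) {
      run_cost(c(s[1] - 1, diff(s) - 1, lb - s[k]))
    })
    sub <- matrix(0, ncol(SA), ncol(SB))
    for (i in seq_len(k)) {
      sub <- sub + matrix(M[av[SA[i, ]], bv[SB[i, ]]],
                          nrow = ncol(SA), ncol = ncol(SB))
    }
    best <- max(best, max(sub + outer(ga, gb, "+")))
  }
  best
}

# One-sided Fisher p-value by direct hypergeometric summation with lchoose.
oracle_fisher_tail <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n <- a + b
  j <- a:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# Random sense-codon pair: ancestor plus a mutated partner with per-codon
# mutation probability p_mut (stop codons rejected).
random_codon_pair <- function(n_codons, p_mut = 0.3) {
  sense <- oracle_sense_codons()
  gc <- oracle_code()
  a <- sample(sense, n_codons, replace = TRUE)
  b <- a
  for (i in seq_len(n_codons)) {
    if (stats::runif(1) < p_mut) {
      repeat {
        cand <- b[i]
        pos <- sample(3, 1)
        substr(cand, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
        if (cand != b[i] && gc[[cand]] != "*") {
          b[i] <- cand
          break
        }
      }
    }
  }
  list(a = a, b = b)
}

# Gapless codon alignment from two equal-length codon vectors, via the
# package's own back-translation (no gaps are introduced because the
# "aligned" peptides are the plain translations).
codon_aln_from_codons <- function(codons_a, codons_b) {
  cds_a <- paste(codons_a, collapse = "")
  cds_b <- paste(codons_b, collapse = "")
  back_translate(translate_cds(cds_a), translate_cds(cds_b), cds_a, cds_b)
}

# Small simulation config for fast tests.
tiny_config <- function(...) {
  simulation_config(
    seed = 11, n_wgd_pairs = 5, n_tandem_pairs = 2, n_singletons = 5,
    n_codons_range = c(180, 240), ...
  )
}
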