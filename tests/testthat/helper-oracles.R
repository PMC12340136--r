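# Independent oracles used across the suite. Each re-derives the expected
# behavior by brute force or textbook formulas, separately from the package
# code paths it checks.

# Exhaustive tryptic digestion: enumerate every contiguous run of the
# fragments obtained by cutting at all strict-trypsin sites, keeping runs
# with <= max_missed internal sites, then length-filter.
oracle_digest <- function(seq, max_missed = 3, min_len = 4, max_len = 60) {
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(res)
  cut_after <- logical(n)
  for (i in seq_len(n - 1)) {
    if (res[i] %in% c("K", "R") && res[i + 1] != "P") cut_after[i] <- TRUE
  }
  frag_start <- c(1L, which(cut_after) + 1L)
  frag_end <- c(which(cut_after), n)
  nf <- length(frag_start)
  out <- list()
  for (a in seq_len(nf)) for (b in a:min(nf, a + max_missed)) {
    s <- frag_start[a]; e <- frag_end[b]
    len <- e - s + 1L
    if (len >= min_len && len <= max_len) {
      out[[length(out) + 1L]] <- c(start = s, end = e, missed = b - a)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), missed = integer(0)))
  }
  d <- as.data.frame(do.call(rbind, out))
  d <- d[order(d$start, d$end), , drop = FALSE]
  rownames(d) <- NULL
  d
}

# Independent residue-by-residue mass summation over the same constant table.
oracle_peptide_mass <- function(seq) {
  tbl <- residue_masses()
  total <- 0
  for (r in strsplit(seq, "", fixed = TRUE)[[1]]) total <- total + tbl[[r]]
  total + WATER_MASS
}

# Textbook two-sided two-sample t-test (pooled and Welch variants).
oracle_t_p <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    tstat <- (mean(b) - mean(a)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    tstat <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  2 * pt(-abs(tstat), df)
}

# Prefix/suffix b/y ladder for an unmodified linear peptide at charge z,
# with an optional extra mass placed on one residue.
oracle_by_ladder <- function(seq, z = 1, extra_on = NA, extra_mass = 0) {
  tbl <- residue_masses()
  res <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- tbl[res]
  if (!is.na(extra_on)) m[extra_on] <- m[extra_on] + extra_mass
  n <- length(m)
  b <- sapply(1:(n - 1), function(i) sum(m[1:i]))
  y <- sapply(1:(n - 1), function(j) sum(m[(n - j + 1):n]) + WATER_MASS)
  list(b = (b + z * PROTON_MASS) / z, y = (y + z * PROTON_MASS) / z)
}

# Closed-form simple-regression solution from the normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  c(slope = slope, intercept = intercept)
}

# Coarse grid search + golden refinement for the one-phase decay minimum.
oracle_decay_grid <- function(x, y, kmax = 50) {
  ss_for <- function(k) {
    e <- exp(-k * x)
    fit <- lm(y ~ e)
    sum(resid(fit)^2)
  }
  ks <- 10^seq(-3, log10(kmax), length.out = 400)
  ss <- vapply(ks, ss_for, numeric(1))
  kbest <- ks[which.min(ss)]
  opt <- optimize(ss_for, interval = c(kbest / 3, kbest * 3))
  e <- exp(-opt$minimum * x)
  fit <- lm(y ~ e)
  co <- coef(fit)
  list(k = opt$minimum, plateau = unname(co[1]),
       y0 = unname(co[1] + co[2]), ss = opt$objective)
}

random_protein <- function(len, alphabet = canonical_residues()) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
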