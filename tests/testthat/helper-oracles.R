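# Independent oracles used to cross-check the package implementations.
# Each is written as a direct enumeration / hand computation, deliberately
# not sharing code with the package.

# Exact HWE p by explicit enumeration: condition on the observed allele
# counts, enumerate every compatible genotype table, and compute each
# table's probability by counting allele-to-genotype pairings.
oracle_hwe_exact <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na_al <- 2 * n_aa + n_ab
  nb_al <- 2 * n - na_al
  if (na_al == 0 || nb_al == 0) return(1)
  hets <- seq(na_al %% 2, min(na_al, nb_al), by = 2)
  count_ways <- function(h) {
    a <- (na_al - h) / 2
    b <- (nb_al - h) / 2
    # multinomial arrangements of individuals times het phasings
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) + h * log(2)
  }
  lw <- vapply(hets, count_ways, numeric(1))
  pr <- exp(lw - max(lw))
  pr <- pr / sum(pr)
  p_obs <- pr[hets == n_ab]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# Hand Benjamini-Hochberg: p_(i) * m / i then cumulative minimum from the
# right, mapped back to the original order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  q <- numeric(m)
  q[o] <- pmin(adj, 1)
  q
}

# Brute-force clumping: literal re-enactment of the greedy rule with
# scalar loops and no vectorized shortcuts.
oracle_clump <- function(res, variants, dosages, p_threshold, r2_threshold,
                         window_bp) {
  df <- merge(as.data.frame(res), as.data.frame(variants), by = "variant_id")
  df <- df[!is.na(df$p) & df$p < p_threshold, ]
  df <- df[order(df$p), ]
  out <- list()
  while (nrow(df) > 0) {
    lead <- df[1, ]
    member_idx <- c()
    for (i in seq_len(nrow(df))) {
      if (df$chrom[i] == lead$chrom && abs(df$pos[i] - lead$pos) <= window_bp) {
        member_idx <- c(member_idx, i)
      }
    }
    extras <- character(0)
    for (i in member_idx) {
      v <- df$variant_id[i]
      if (v == lead$variant_id) next
      r <- suppressWarnings(cor(dosages[, lead$variant_id], dosages[, v],
                                use = "pairwise.complete.obs"))
      if (!is.na(r) && r * r < r2_threshold) extras <- c(extras, v)
    }
    out[[length(out) + 1]] <- list(lead = lead$variant_id,
                                   n_signals = 1L + length(extras))
    df <- df[-member_idx, ]
  }
  out
}

# Population stage-2 probe-weight vector for the generator's probe model:
# with l2r_p = a_p c + b_p + eps_p, eps_p ~ N(0, s_p^2 * E[scale^2]), the
# coefficient vector of the regression of (c + coverage noise) on the
# selected probes is  sigma_c^2 (Sigma)^-1 A  with
# Sigma = A A' sigma_c^2 + D; computed via Sherman-Morrison.
oracle_population_weights <- function(gain, noise_sd, var_c, e_scale2) {
  d_inv <- 1 / (noise_sd^2 * e_scale2)
  denom <- 1 + var_c * sum(gain^2 * d_inv)
  var_c * d_inv * gain / denom
}
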