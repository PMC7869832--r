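# Case-control association scan and fixed-effects meta-analysis.

#' Allele-count case-control association scan
#'
#' For every variant with study-sample MAF strictly above `maf_threshold`,
#' builds the 2x2 allele-count table (case/control x effect/other allele)
#' and reports `OR = (a*d)/(b*c)`, `SE(log OR) = sqrt(1/a+1/b+1/c+1/d)`,
#' and the 1-df chi-square statistic without continuity correction. The
#' effect allele is the minor allele in the study sample (recorded as
#' "ALT" or "REF" so cross-population weight transfer is unambiguous).
#' Tables with a zero cell get the Haldane-Anscombe +0.5 correction for
#' the OR and SE only (the test statistic is unchanged) and are flagged.
#'
#' @param panel a `haplotype_panel`.
#' @param cases,controls disjoint, non-empty integer vectors of diploid
#'   indices into `panel`.
#' @param maf_threshold exclusive MAF cutoff (default 0.01: keep MAF > 1%).
#' @return An `assoc_result` data.frame with columns `variant_id`, `pos`,
#'   `site_index`, `effect_allele`, `maf`, `alt_freq`, `or`, `log_or`,
#'   `se`, `chisq`, `p`, `zero_cell`; attributes `population`, `n_cases`,
#'   `n_controls`.
#' @export
association_scan <- function(panel, cases, controls, maf_threshold = 0.01) {
  stopifnot(length(cases) > 0, length(controls) > 0)
  if (length(intersect(cases, controls)) > 0)
    stop("case and control sets must be disjoint")

  case_haps <- as.vector(rbind(2L * cases - 1L, 2L * cases))
  ctrl_haps <- as.vector(rbind(2L * controls - 1L, 2L * controls))
  alt_case <- colSums(hap_int(panel, case_haps))
  alt_ctrl <- colSums(hap_int(panel, ctrl_haps))
  n_case_al <- 2 * length(cases)
  n_ctrl_al <- 2 * length(controls)

  alt_f <- (alt_case + alt_ctrl) / (n_case_al + n_ctrl_al)
  maf <- pmin(alt_f, 1 - alt_f)
  keep <- which(maf > maf_threshold)
  if (length(keep) == 0) {
    warning("no variant passes the MAF filter")
  }

  effect_is_alt <- alt_f[keep] <= 0.5
  a <- ifelse(effect_is_alt, alt_case[keep], n_case_al - alt_case[keep])
  b <- n_case_al - a
  c_ <- ifelse(effect_is_alt, alt_ctrl[keep], n_ctrl_al - alt_ctrl[keep])
  d <- n_ctrl_al - c_

  n_tot <- n_case_al + n_ctrl_al
  num <- (a * d - b * c_)^2 * n_tot
  den <- as.double(n_case_al) * n_ctrl_al * (a + c_) * (b + d)
  chisq <- num / den
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)

  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  a2 <- a + 0.5 * zero; b2 <- b + 0.5 * zero
  c2 <- c_ + 0.5 * zero; d2 <- d + 0.5 * zero
  or <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)

  out <- data.frame(
    variant_id = sprintf("v%d", panel$positions[keep]),
    pos = panel$positions[keep],
    site_index = keep,
    effect_allele = ifelse(effect_is_alt, "ALT", "REF"),
    maf = maf[keep],
    alt_freq = alt_f[keep],
    or = or, log_or = log(or), se = se,
    chisq = chisq, p = p,
    zero_cell = zero)
  structure(out, population = panel$population,
            n_cases = length(cases), n_controls = length(controls),
            class = c("assoc_result", "data.frame"))
}

#' Fixed-effects inverse-variance meta-analysis of two scans
#'
#' Combines two association scans over their shared variants:
#' `meta log OR = sum(w_i b_i) / sum(w_i)` with `w_i = 1/SE_i^2`, `meta SE
#' = sum(w_i)^(-1/2)`, p-value from the normal approximation, plus
#' Cochran's Q (1 df) and I^2. Effects are aligned to the ALT allele
#' before combining, then reported on the combined-sample minor allele.
#' Variants present in only one study are excluded (count reported as an
#' attribute).
#'
#' @param res_a,res_b `assoc_result` objects over the same coordinate
#'   space.
#' @return An `assoc_result`-like data.frame with meta columns `q`,
#'   `q_p`, `i2`, `heterogeneous` (I^2 > 25% and Q p < 0.05).
#' @export
meta_analyze <- function(res_a, res_b) {
  m <- merge(as.data.frame(res_a), as.data.frame(res_b),
             by = c("variant_id", "pos", "site_index"),
             suffixes = c("_a", "_b"))
  if (nrow(m) == 0) stop("no shared variants between the two studies")
  n_dropped <- (nrow(res_a) - nrow(m)) + (nrow(res_b) - nrow(m))

  # align both studies to the ALT allele
  b_a <- ifelse(m$effect_allele_a == "ALT", m$log_or_a, -m$log_or_a)
  b_b <- ifelse(m$effect_allele_b == "ALT", m$log_or_b, -m$log_or_b)
  w_a <- 1 / m$se_a^2
  w_b <- 1 / m$se_b^2
  beta <- (w_a * b_a + w_b * b_b) / (w_a + w_b)
  se <- 1 / sqrt(w_a + w_b)
  q <- w_a * (b_a - beta)^2 + w_b * (b_b - beta)^2
  i2 <- pmax(0, (q - 1) / q) * 100
  q_p <- stats::pchisq(q, df = 1, lower.tail = FALSE)

  n_a <- attr(res_a, "n_cases") + attr(res_a, "n_controls")
  n_b <- attr(res_b, "n_cases") + attr(res_b, "n_controls")
  alt_f <- (m$alt_freq_a * n_a + m$alt_freq_b * n_b) / (n_a + n_b)
  effect_is_alt <- alt_f <= 0.5
  log_or <- ifelse(effect_is_alt, beta, -beta)
  z <- beta / se
  out <- data.frame(
    variant_id = m$variant_id, pos = m$pos, site_index = m$site_index,
    effect_allele = ifelse(effect_is_alt, "ALT", "REF"),
    maf = pmin(alt_f, 1 - alt_f), alt_freq = alt_f,
    or = exp(log_or), log_or = log_or, se = se,
    chisq = z^2, p = 2 * stats::pnorm(-abs(z)),
    zero_cell = m$zero_cell_a | m$zero_cell_b,
    maf_a = m$maf_a, maf_b = m$maf_b,
    q = q, q_p = q_p, i2 = i2,
    heterogeneous = i2 > 25 & q_p < 0.05)
  out <- out[order(out$site_index), ]
  rownames(out) <- NULL
  structure(out, population = "META",
            n_cases = attr(res_a, "n_cases") + attr(res_b, "n_cases"),
            n_controls = attr(res_a, "n_controls") + attr(res_b, "n_controls"),
            n_dropped_unshared = n_dropped,
            class = c("assoc_result", "data.frame"))
}
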