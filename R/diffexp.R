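#' Two-group tissue-vs-rest linear fit per transcript
#'
#' For each transcript, fits the two-group model contrasting samples of the
#' target tissue against all remaining samples on the log2 scale:
#' `effect = mean(target) - mean(rest)`, with the pooled residual variance
#' on `n - 2` degrees of freedom.
#'
#' @param m log2 expression matrix (transcripts x samples).
#' @param tissue_of named character vector: sample id -> tissue code.
#' @param target_tissue tissue to contrast against the rest.
#' @return data.frame with `effect`, `s2` (pooled residual variance), `df`,
#'   plus attributes `n_target` and `n_rest`.
#' @export
fit_tissue_vs_rest <- function(m, tissue_of, target_tissue) {
  if (em_scale(m) != "log2")
    warning("expected a log2-scale matrix (em_scale != 'log2')")
  tissue_of <- tissue_of[colnames(m)]
  in_target <- !is.na(tissue_of) & tissue_of == target_tissue
  n1 <- sum(in_target); n2 <- sum(!in_target)
  if (n1 < 2) stop("tissue '", target_tissue, "' has fewer than 2 samples")
  if (n2 < 2) stop("rest-of-samples group for '", target_tissue,
                   "' has fewer than 2 samples")
  x1 <- m[, in_target, drop = FALSE]
  x2 <- m[, !in_target, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
  df <- n1 + n2 - 2L
  out <- data.frame(effect = m1 - m2, s2 = ss / df, df = df,
                    row.names = rownames(m))
  attr(out, "n_target") <- n1
  attr(out, "n_rest") <- n2
  out
}

#' Empirical-Bayes prior for residual variances
#'
#' Method-of-moments fit on the log residual variances: under the scaled
#' F / log-chi-square theory, `log(s2)` has mean
#' `log(s0_sq) + digamma(df/2) - log(df/2) - digamma(d0/2) + log(d0/2)` and
#' excess variance `trigamma(d0/2)` beyond the sampling term
#' `trigamma(df/2)`. Matching both moments yields the prior degrees of
#' freedom `d0` and prior variance `s0_sq`. When the empirical variance of
#' `log(s2)` does not exceed the sampling term, the variances are treated as
#' homogeneous: `d0 = Inf` and `s0_sq` is the geometric mean of the observed
#' variances (so all-equal variances `v` recover `s0_sq = v` exactly).
#'
#' @param s2 per-transcript residual variances (>= 10 positive values).
#' @param df residual degrees of freedom (scalar or vector).
#' @return object of class `EBPrior`: list with `d0` and `s0_sq`.
#' @export
estimate_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok)) stop("all residual variances are zero: degenerate input")
  if (sum(ok) < 10)
    stop("need at least 10 transcripts with positive variance and df")
  z <- log(s2[ok]); dfo <- df[ok]
  e <- z - digamma(dfo / 2) + log(dfo / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dfo / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- exp(mean(z))
  }
  structure(list(d0 = d0, s0_sq = s0_sq), class = "EBPrior")
}

# Solve trigamma(y) = x by Newton iteration on 1/y (monotone, stable).
trigamma_inverse <- function(x) {
  if (x <= 0) stop("trigamma_inverse needs a positive argument")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Moderated t-statistic
#'
#' Shrinks each transcript's residual variance toward the prior:
#' `s2_tilde = (d0 * s0_sq + df * s2) / (d0 + df)`, then
#' `t = effect / sqrt(s2_tilde * (1/n1 + 1/n2))` with a two-sided p-value on
#' `df + d0` degrees of freedom. An infinite `d0` (homogeneous variances) is
#' treated as the no-moderation case: the statistic reduces exactly to the
#' classical pooled-variance two-sample t on `df` degrees of freedom, which
#' also keeps null p-values exactly uniform.
#'
#' @param fit a [fit_tissue_vs_rest()] result (or any data.frame with
#'   `effect`, `s2`, `df`).
#' @param prior an [estimate_prior()] result.
#' @param n_target,n_rest group sizes; default taken from `fit` attributes.
#' @return data.frame with `t_mod`, `p`, `df_total`, and `zero_variance`
#'   flag (`s2_tilde == 0`: t reported infinite, p = 0).
#' @export
moderated_t <- function(fit, prior, n_target = NULL, n_rest = NULL) {
  stopifnot(inherits(prior, "EBPrior"))
  n1 <- n_target %||% attr(fit, "n_target")
  n2 <- n_rest %||% attr(fit, "n_rest")
  if (is.null(n1) || is.null(n2)) stop("group sizes unavailable")
  d0 <- prior$d0
  if (is.finite(d0)) {
    s2_tilde <- (d0 * prior$s0_sq + fit$df * fit$s2) / (d0 + fit$df)
    df_total <- fit$df + d0
  } else {
    s2_tilde <- fit$s2
    df_total <- fit$df
  }
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  t_mod <- fit$effect / se
  zero <- s2_tilde == 0
  t_mod[zero] <- ifelse(fit$effect[zero] == 0, 0, Inf * sign(fit$effect[zero]))
  p <- 2 * stats::pt(abs(t_mod), df = df_total, lower.tail = FALSE)
  p[zero & fit$effect == 0] <- 1
  data.frame(t_mod = t_mod, p = p, df_total = rep_len(df_total, length(t_mod)),
             zero_variance = zero, row.names = rownames(fit))
}

#' Tissue-differential expression across all tissues
#'
#' Runs [fit_tissue_vs_rest()] + empirical-Bayes moderation for every tissue
#' and assembles the per-(transcript, tissue) table: log2 fold change,
#' moderated t, p, BH-adjusted q (across the whole table), and the
#' stringent-pass flag `|fold change| > fc_cut` and `p < p_cut`.
#'
#' @param m log2 expression matrix.
#' @param tissue_of named character vector: sample -> tissue.
#' @param fc_cut fold-change threshold on the natural scale (default 5).
#' @param p_cut p-value threshold (default 1e-6).
#' @param tissues tissues to test (default: all in `tissue_of`).
#' @return data.frame of class `DEResult` with `transcript`, `tissue`,
#'   `log2_fc`, `t_mod`, `p`, `q`, `df_total`, `passes_filter`.
#' @export
tissue_de <- function(m, tissue_of, fc_cut = 5.0, p_cut = 1e-6,
                      tissues = NULL) {
  tissue_of <- tissue_of[colnames(m)]
  tissues <- tissues %||% unique(tissue_of)
  rows <- lapply(tissues, function(tt) {
    fit <- fit_tissue_vs_rest(m, tissue_of, tt)
    prior <- estimate_prior(fit$s2, fit$df)
    mt <- moderated_t(fit, prior)
    data.frame(transcript = rownames(fit), tissue = tt,
               log2_fc = fit$effect, t_mod = mt$t_mod, p = mt$p,
               df_total = mt$df_total, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  de <- do.call(rbind, rows)
  de$q <- bh_adjust(de$p)
  de$passes_filter <- abs(de$log2_fc) > log2(fc_cut) & de$p < p_cut
  class(de) <- c("DEResult", "data.frame")
  attr(de, "fc_cut") <- fc_cut
  attr(de, "p_cut") <- p_cut
  de
}

#' Apply the stringent tissue-specificity filter
#'
#' A transcript passes when it shows significant up- or down-regulation in
#' at least one tissue: `|log2 fold change| > log2(fc_cut)` and
#' `p < p_cut` in some tissue.
#'
#' @param de a [tissue_de()] table.
#' @param fc_cut fold-change threshold, natural scale (default 5.0).
#' @param p_cut p-value threshold (default 1e-6).
#' @return character vector of passing transcript ids.
#' @export
apply_filter <- function(de, fc_cut = 5.0, p_cut = 1e-6) {
  pass <- abs(de$log2_fc) > log2(fc_cut) & de$p < p_cut
  unique(de$transcript[pass])
}
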