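#' Descriptive summary of one wave
#'
#' Per node: sample size, mean, standard deviation, median and quartiles
#' (linear-interpolation convention, the default of [stats::quantile()]).
#' Counts and percentages are returned for any categorical covariates
#' supplied alongside the node columns.
#'
#' @param panel A `symptom_panel`.
#' @param wave Wave label (`"T0"` or `"T1"`).
#' @param covariates Optional data frame of per-subject categorical
#'   covariates (`subject_id` plus factor/character columns).
#' @return Tibble with columns `node`, `n`, `mean`, `sd`, `median`, `q25`,
#'   `q75`; covariate level counts, if requested, in
#'   `attr(, "covariate_counts")`.
#' @export
describe_panel <- function(panel, wave, covariates = NULL) {
  if (!wave %in% panel$wave) stop("wave ", wave, " not present", call. = FALSE)
  nodes <- panel_nodes(panel)
  sl <- panel[panel$wave == wave, nodes, drop = FALSE]
  if (nrow(sl) == 0) stop("wave ", wave, " is empty", call. = FALSE)
  out <- purrr::map_dfr(nodes, function(nd) {
    v <- sl[[nd]]
    v <- v[!is.na(v)]
    tibble::tibble(
      node = nd,
      n = length(v),
      mean = mean(v),
      sd = sd(v),
      median = median(v),
      q25 = unname(quantile(v, 0.25)),
      q75 = unname(quantile(v, 0.75))
    )
  })
  if (!is.null(covariates)) {
    cc <- covariates[setdiff(names(covariates), "subject_id")]
    counts <- purrr::imap_dfr(cc, function(v, nm) {
      tb <- table(v)
      tibble::tibble(variable = nm, level = names(tb),
                     count = as.integer(tb),
                     percent = 100 * as.integer(tb) / sum(tb))
    })
    attr(out, "covariate_counts") <- counts
  }
  out
}

#' Paired T0-versus-T1 comparison with normality branching
#'
#' Shapiro-Wilk normality of the paired differences decides the test: the
#' paired t test when `normality_p >= alpha_normality`, otherwise the
#' Wilcoxon signed-rank test (zero differences dropped, ties mid-ranked,
#' continuity-corrected normal approximation for more than 25 nonzero
#' pairs, exact distribution below). For the Wilcoxon branch the reported
#' statistic is the normal-approximation z; positive and negative rank
#' sums are returned alongside.
#'
#' @param x0,x1 Paired numeric vectors (equal length >= 10); incomplete
#'   pairs are removed.
#' @param alpha_normality Normality cutoff for the branch decision.
#' @param node Optional node label carried into the result.
#' @return One-row tibble (class `paired_comparison`): `node`, `n_pairs`,
#'   per-wave `mean`/`sd`/`median`/`q25`/`q75`, `normality_p`, `test_used`
#'   (`"paired_t"`, `"wilcoxon_signed_rank"` or `"degenerate"`),
#'   `statistic`, `w_plus`, `w_minus`, `p_value`.
#' @export
paired_compare <- function(x0, x1, alpha_normality = 0.05, node = NA_character_) {
  if (length(x0) != length(x1)) stop("`x0` and `x1` must be paired", call. = FALSE)
  ok <- !is.na(x0) & !is.na(x1)
  x0 <- x0[ok]
  x1 <- x1[ok]
  n <- length(x0)
  if (n < 10) stop("need at least 10 complete pairs", call. = FALSE)
  d <- x1 - x0
  s <- function(v) {
    list(mean = mean(v), sd = sd(v), median = median(v),
         q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)))
  }
  s0 <- s(x0)
  s1 <- s(x1)
  base <- tibble::tibble(
    node = node, n_pairs = n,
    mean_t0 = s0$mean, sd_t0 = s0$sd, median_t0 = s0$median,
    q25_t0 = s0$q25, q75_t0 = s0$q75,
    mean_t1 = s1$mean, sd_t1 = s1$sd, median_t1 = s1$median,
    q25_t1 = s1$q25, q75_t1 = s1$q75
  )
  if (all(d == 0)) {
    out <- dplyr::mutate(base, normality_p = NA_real_,
                         test_used = "degenerate", statistic = NA_real_,
                         w_plus = NA_real_, w_minus = NA_real_,
                         p_value = NA_real_)
    return(structure(out, class = c("paired_comparison", class(out))))
  }
  dn <- d[d != 0]
  norm_p <- if (length(unique(d)) < 3) 0 else {
    shapiro.test(d[seq_len(min(n, 5000))])$p.value
  }
  if (norm_p >= alpha_normality) {
    tt <- t.test(x1, x0, paired = TRUE)
    out <- dplyr::mutate(base, normality_p = norm_p, test_used = "paired_t",
                         statistic = unname(tt$statistic),
                         w_plus = NA_real_, w_minus = NA_real_,
                         p_value = tt$p.value)
  } else {
    r <- rank(abs(dn))
    w_plus <- sum(r[dn > 0])
    w_minus <- sum(r[dn < 0])
    m <- length(dn)
    ties <- any(duplicated(abs(dn)))
    mu <- m * (m + 1) / 4
    tie_tab <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    cc <- if (m > 25) 0.5 * sign(w_plus - mu) else 0
    z <- (w_plus - mu - cc) / sqrt(sigma2)
    p <- if (m <= 25 && !ties) {
      wilcox.test(dn, exact = TRUE)$p.value
    } else {
      2 * pnorm(-abs(z))
    }
    out <- dplyr::mutate(base, normality_p = norm_p,
                         test_used = "wilcoxon_signed_rank",
                         statistic = z, w_plus = w_plus, w_minus = w_minus,
                         p_value = p)
  }
  structure(out, class = c("paired_comparison", class(out)))
}

#' Paired comparisons for every node of a panel
#'
#' Runs [paired_compare()] on the completers of each node, producing the
#' familiar clinical-table layout: a per-wave summary (mean +/- sd when the
#' paired t branch was used, median and quartiles otherwise), the test
#' statistic and the p value.
#'
#' @param panel A `symptom_panel` with both waves.
#' @param alpha_normality Normality cutoff for the branch decision.
#' @return Tibble with one row per node.
#' @export
compare_waves <- function(panel, alpha_normality = 0.05) {
  mats <- completer_matrices(panel)
  purrr::map_dfr(colnames(mats$x0), function(nd) {
    paired_compare(mats$x0[, nd], mats$x1[, nd],
                   alpha_normality = alpha_normality, node = nd)
  })
}

#' Format paired comparisons as a report table
#'
#' @param comparisons Output of [compare_waves()].
#' @return Tibble with columns `node`, `summary_t0`, `summary_t1`,
#'   `statistic`, `p_value`, `test_used`: mean +/- sd rows for the paired t
#'   branch, median (q25, q75) rows for the Wilcoxon branch.
#' @export
format_comparison_table <- function(comparisons) {
  fmt <- function(m, sdv, md, q1, q3, t_branch) {
    ifelse(t_branch,
           sprintf("%.2f ± %.2f", m, sdv),
           sprintf("%.2f (%.2f, %.2f)", md, q1, q3))
  }
  dplyr::mutate(
    comparisons,
    t_branch = .data$test_used == "paired_t",
    summary_t0 = fmt(.data$mean_t0, .data$sd_t0, .data$median_t0,
                     .data$q25_t0, .data$q75_t0, .data$t_branch),
    summary_t1 = fmt(.data$mean_t1, .data$sd_t1, .data$median_t1,
                     .data$q25_t1, .data$q75_t1, .data$t_branch)
  ) |>
    dplyr::select("node", "summary_t0", "summary_t1", "statistic",
                  "p_value", "test_used")
}
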