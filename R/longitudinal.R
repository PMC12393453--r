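#' Conservation of activity status across a revisit
#'
#' @param pair Revisit tibble with `status_day0` and `status_dayn`
#'   (`"active"`/`"inactive"`), one row per matched cell.
#' @return One-row tibble: `n`, `n_maintained`, `prop_maintained`,
#'   `prop_active_day0`, `prop_active_dayn`.
#' @export
conservation_stats <- function(pair) {
  stopifnot(all(c("status_day0", "status_dayn") %in% names(pair)))
  if (!nrow(pair)) stop("empty revisit pair")
  tibble(
    n = nrow(pair),
    n_maintained = sum(pair$status_day0 == pair$status_dayn),
    prop_maintained = mean(pair$status_day0 == pair$status_dayn),
    prop_active_day0 = mean(pair$status_day0 == "active"),
    prop_active_dayn = mean(pair$status_dayn == "active")
  )
}

#' Chi-squared test of activity-status conservation
#'
#' Two-category goodness-of-fit test (df = 1) of the observed
#' maintained/not-maintained counts against a "random activity" null. The
#' default null follows the published rule verbatim: the expected maintained
#' proportion equals the day-0 active proportion `expected_p0` (0.58 for
#' 24-hour revisits, 0.54 for 14-day revisits, 0.74 for the knockout
#' 14-day revisits). The statistically standard independence null — a cell
#' is maintained with probability `p0^2 + (1 - p0)^2` when the two days are
#' independent draws at rate `p0` — is computed alongside and labelled, since
#' the two nulls differ.
#'
#' @param pair Revisit tibble (see [conservation_stats()]).
#' @param expected_p0 Day-0 active proportion in (0, 1).
#' @return A `capnet_conservation` object with [tidy()] and [glance()]
#'   methods; fields include `chi2`, `p_value`, `df = 1` and the
#'   independence-null counterparts (`chi2_independence`,
#'   `p_value_independence`, `expected_p_independence`).
#' @export
chi_square_conservation <- function(pair, expected_p0) {
  stopifnot(expected_p0 > 0, expected_p0 < 1)
  cs <- conservation_stats(pair)
  n <- cs$n
  gof <- function(p_exp) {
    exp_m <- p_exp * n
    exp_nm <- (1 - p_exp) * n
    if (min(exp_m, exp_nm) < 1) {
      warning("expected count below 1; chi-squared approximation is unreliable")
    }
    chi2 <- (cs$n_maintained - exp_m)^2 / exp_m +
      ((n - cs$n_maintained) - exp_nm)^2 / exp_nm
    list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
  }
  paper <- gof(expected_p0)
  p_ind <- expected_p0^2 + (1 - expected_p0)^2
  ind <- gof(p_ind)
  structure(
    list(
      n = n, n_maintained = cs$n_maintained,
      prop_maintained = cs$prop_maintained,
      expected_p0 = expected_p0, df = 1L,
      chi2 = paper$chi2, p_value = paper$p,
      expected_p_independence = p_ind,
      chi2_independence = ind$chi2, p_value_independence = ind$p
    ),
    class = "capnet_conservation"
  )
}

#' @export
print.capnet_conservation <- function(x, ...) {
  cat("Activity-status conservation (chi-squared goodness of fit, df = 1)\n")
  cat(sprintf("  n = %d matched cells, %d maintained (%.1f%%)\n",
              x$n, x$n_maintained, 100 * x$prop_maintained))
  cat(sprintf("  day-0 null (p0 = %.2f):        chi2 = %.4f, p = %.4g\n",
              x$expected_p0, x$chi2, x$p_value))
  cat(sprintf("  independence null (p = %.4f): chi2 = %.4f, p = %.4g\n",
              x$expected_p_independence, x$chi2_independence,
              x$p_value_independence))
  invisible(x)
}

#' @rdname chi_square_conservation
#' @param x A `capnet_conservation` object.
#' @param ... Unused.
#' @method tidy capnet_conservation
#' @export
tidy.capnet_conservation <- function(x, ...) {
  tibble(
    null = c("day0_proportion", "independence"),
    expected_proportion = c(x$expected_p0, x$expected_p_independence),
    statistic = c(x$chi2, x$chi2_independence),
    df = 1L,
    p.value = c(x$p_value, x$p_value_independence)
  )
}

#' @rdname chi_square_conservation
#' @method glance capnet_conservation
#' @export
glance.capnet_conservation <- function(x, ...) {
  tibble(
    n = x$n, prop_maintained = x$prop_maintained,
    statistic = x$chi2, df = 1L, p.value = x$p_value
  )
}

#' Retention of high-dynamics classes across a revisit
#'
#' For each class column pair present (`high_frequency_day0` /
#' `high_frequency_dayn`, `high_avg_duration_*`, `persistent_*`), computes
#' the fraction of day-0 class members that hold the class on the revisit,
#' plus the Venn counts (day-0 only, day-N only, both) behind the published
#' retention maps. Classes must have been assigned with day-0 (or control)
#' reference thresholds on both days.
#'
#' @param pair Revisit tibble with logical class columns as above.
#' @return Tibble `class`, `n_day0`, `n_dayn`, `n_both`, `n_day0_only`,
#'   `n_dayn_only`, `retention` (`NA` when no day-0 members).
#' @export
dynamics_retention <- function(pair) {
  classes <- c("high_frequency", "high_avg_duration", "persistent")
  out <- lapply(classes, function(cl) {
    c0 <- pair[[paste0(cl, "_day0")]]
    cn <- pair[[paste0(cl, "_dayn")]]
    if (is.null(c0) || is.null(cn)) return(NULL)
    n0 <- sum(c0, na.rm = TRUE)
    nn <- sum(cn, na.rm = TRUE)
    nb <- sum(c0 & cn, na.rm = TRUE)
    tibble(
      class = cl, n_day0 = n0, n_dayn = nn, n_both = nb,
      n_day0_only = n0 - nb, n_dayn_only = nn - nb,
      retention = if (n0 > 0) nb / n0 else NA_real_
    )
  })
  out <- bind_rows(out)
  if (!nrow(out)) stop("no class column pairs (e.g. high_frequency_day0/_dayn) found")
  out
}

#' Per-mouse percent change of dynamics summaries across treatment
#'
#' Computes, per mouse and metric, the percent change of the per-mouse mean
#' between the pre- and post-treatment recordings:
#' `100 * (post - pre) / pre`. Mice with a zero pre-treatment mean are
#' excluded for that metric with a warning.
#'
#' @param pre,post Tibbles with a `mouse` column and one numeric column per
#'   metric (e.g. per-mouse means of `active_prop`, `frequency`,
#'   `avg_duration`, `persistent_cluster_size`), one row per mouse.
#' @return Tibble `mouse`, `metric`, `pre`, `post`, `pct_change`.
#' @export
treatment_percent_change <- function(pre, post) {
  stopifnot("mouse" %in% names(pre), "mouse" %in% names(post))
  long <- function(d, nm) {
    tidyr::pivot_longer(d, -"mouse", names_to = "metric", values_to = nm)
  }
  out <- inner_join(long(pre, "pre"), long(post, "post"),
                    by = c("mouse", "metric")) %>%
    mutate(pct_change = 100 * (.data$post - .data$pre) / .data$pre)
  zero <- out %>% filter(.data$pre == 0)
  if (nrow(zero)) {
    warning("pre-treatment mean is zero; percent change undefined and excluded for: ",
            paste(paste(zero$mouse, zero$metric, sep = "/"), collapse = ", "))
    out <- out %>% filter(.data$pre != 0)
  }
  out
}

#' Compare per-mouse percent changes between two treatment groups
#'
#' Unpaired two-tailed t-test per metric on the per-mouse percent changes
#' (pooled-variance Student's test by default; set `welch = TRUE` for the
#' Welch correction).
#'
#' @param changes_a,changes_b Outputs of [treatment_percent_change()] for the
#'   two groups.
#' @param welch Use Welch's unequal-variance correction (default `FALSE`).
#' @return Tibble `metric`, `mean_a`, `mean_b`, `statistic`, `df`, `p.value`.
#' @export
compare_treatment_groups <- function(changes_a, changes_b, welch = FALSE) {
  metrics <- intersect(unique(changes_a$metric), unique(changes_b$metric))
  out <- lapply(metrics, function(m) {
    a <- changes_a$pct_change[changes_a$metric == m]
    b <- changes_b$pct_change[changes_b$metric == m]
    tt <- t.test(a, b, var.equal = !welch)
    tibble(
      metric = m, mean_a = mean(a), mean_b = mean(b),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value
    )
  })
  bind_rows(out)
}
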