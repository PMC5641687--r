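#' Run the longitudinal measurement-invariance ladder
#'
#' Fits the configural, strong and strict two-wave models on the same
#' first-stage statistics, computes scaled chi-square difference tests and
#' changes in fit indices between adjacent steps, and applies the
#' change-in-fit decision rules: a more restrictive level is accepted when
#' the RMSEA increase is below `rules$rmsea` (default 0.015) and the CFI and
#' TLI decreases are below `rules$cfi`/`rules$tli` (default 0.01).  The
#' difference-test p-values are reported but are not decisive (index changes
#' take precedence).
#'
#' @param items item tibble ([read_items()] layout), already
#'   analytic-filtered.
#' @param item_info optional tibble `item`, `trait`; by default traits are
#'   inferred from the leading letter of the item name (`e` = extraversion,
#'   `n` = neuroticism), falling back to a single factor.
#' @param rules list of Delta-index thresholds.
#' @param n sample size for test statistics (default: rows of the wide
#'   table).
#' @return object of class `invariance_ladder`: list with `fits`, `summary`
#'   (per-step fit indices), `diffs`, `deltas`, `decision`, `rules`.
#' @export
run_invariance <- function(items, item_info = NULL,
                           rules = list(rmsea = 0.015, cfi = 0.01,
                                        tli = 0.01),
                           n = NULL) {
  its <- item_columns(items)
  if (length(unique(items$wave)) < 2) {
    stop("the invariance ladder needs items observed at two waves",
         call. = FALSE)
  }
  if (is.null(item_info)) {
    lead <- substr(its, 1, 1)
    trait <- ifelse(lead == "n", "neuroticism",
                    ifelse(lead == "e", "extraversion", "trait"))
    item_info <- tibble::tibble(item = its, trait = trait)
  }
  specs <- build_ladder_specs(item_info)
  wide <- items_wide(items)
  vars <- specs$configural$vars$var
  pm <- polychoric_matrix(wide[vars])
  if (is.null(n)) n <- nrow(wide)

  fits <- list()
  for (step in names(specs)) {
    fits[[step]] <- fit_dwls(specs[[step]], pm, n = n)
    if (!fits[[step]]$converged) {
      warning("ladder truncated: ", step, " model did not converge ",
              "(gradient norm ", signif(fits[[step]]$grad_norm, 3), ")",
              call. = FALSE)
      break
    }
  }

  summary <- dplyr::bind_rows(lapply(names(fits), function(s) {
    f <- fits[[s]]
    tibble::tibble(model = s, n = f$n, chi2 = f$chi2, df = f$df,
                   free_parameters = length(f$estimates),
                   rmsea = f$rmsea, cfi = f$cfi, tli = f$tli)
  }))

  steps <- names(fits)
  diffs <- NULL; deltas <- NULL
  if (length(steps) >= 2) {
    for (k in 2:length(steps)) {
      d <- chi2_diff_test(fits[[steps[k]]], fits[[steps[k - 1]]])
      diffs <- dplyr::bind_rows(diffs, tibble::tibble(
        comparison = paste(steps[k], "vs", steps[k - 1]),
        stat = d$stat, df = d$df, p = d$p))
      deltas <- dplyr::bind_rows(deltas, tibble::tibble(
        comparison = paste(steps[k], "vs", steps[k - 1]),
        d_rmsea = fits[[steps[k]]]$rmsea - fits[[steps[k - 1]]]$rmsea,
        d_cfi = fits[[steps[k - 1]]]$cfi - fits[[steps[k]]]$cfi,
        d_tli = fits[[steps[k - 1]]]$tli - fits[[steps[k]]]$tli))
    }
  }

  decision <- invariance_decision(steps, deltas, rules)

  structure(list(fits = fits, summary = summary, diffs = diffs,
                 deltas = deltas, decision = decision, rules = rules),
            class = "invariance_ladder")
}

# pure function of the fitted deltas and the rules; monotone by construction
invariance_decision <- function(steps, deltas, rules) {
  accepted <- steps[1]
  if (is.null(deltas)) return(accepted)
  for (k in seq_len(nrow(deltas))) {
    ok <- deltas$d_rmsea[k] < rules$rmsea &&
      deltas$d_cfi[k] < rules$cfi &&
      deltas$d_tli[k] < rules$tli
    if (!ok) break
    accepted <- steps[k + 1]
  }
  accepted
}

#' @export
print.invariance_ladder <- function(x, ...) {
  cat("Longitudinal measurement invariance ladder\n")
  print(x$summary)
  if (!is.null(x$diffs)) {
    cat("\nScaled chi-square difference tests:\n"); print(x$diffs)
    cat("\nChanges in fit indices:\n"); print(x$deltas)
  }
  cat("\nAccepted level:", x$decision, "\n")
  invisible(x)
}

#' @export
#' @exportS3Method generics::tidy
tidy.invariance_ladder <- function(x, ...) x$summary

#' @export
#' @exportS3Method generics::glance
glance.invariance_ladder <- function(x, ...) {
  tibble::tibble(decision = x$decision,
                 steps_fitted = length(x$fits),
                 all_converged = all(vapply(x$fits, `[[`, TRUE, "converged")))
}

#' @importFrom ggplot2 autoplot
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.invariance_ladder <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              cols = c("rmsea", "cfi", "tli"),
                              names_to = "index", values_to = "value")
  long$model <- factor(long$model, levels = object$summary$model)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     group = .data$index)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Fit indices along the invariance ladder") +
    ggplot2::theme_minimal()
}
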