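#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-class GMM fit
#'
#' One row per mixture component with its estimated parameters.
#'
#' @param x a [fit_gmm_two_class()] result.
#' @param ... unused.
#' @return Tibble: `component`, `class`, `mean`, `sd`, `weight`.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(component = 1:2,
                 class = c("background", "positive"),
                 mean = x$means, sd = x$sds, weight = x$weights)
}

#' @rdname tidy.gmm_fit
#' @return `glance()`: one row with `log_lik`, `n_iter`, `converged`,
#'   `variance`, `seed`.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(log_lik = utils::tail(x$loglik, 1), n_iter = x$n_iter,
                 converged = x$converged, variance = x$variance,
                 seed = x$seed)
}

#' Tidy registration results
#'
#' `tidy()` returns the per-section QC table (Dice of the registered tissue
#' mask against the reference); `glance()` the stack-level summary.
#'
#' @param x an `mx_registration` from [register_stack()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.mx_registration <- function(x, ...) x$qc

#' @rdname tidy.mx_registration
#' @export
glance.mx_registration <- function(x, ...) {
  tibble::tibble(n_sections = nrow(x$qc),
                 reference_index = x$reference_index,
                 mean_dsc = mean(x$qc$dsc),
                 min_dsc = min(x$qc$dsc),
                 mean_adjacent_ncc = mean(x$adjacent$ncc, na.rm = TRUE),
                 all_converged = all(x$qc$converged))
}

#' Summaries of a pipeline run
#'
#' @param x an `mx_run_report` from [run_pipeline()].
#' @param ... unused.
#' @return `tidy()`: the per-stage status table; `glance()`: one row with
#'   headline counts and QC.
#' @export
tidy.mx_run_report <- function(x, ...) x$stages

#' @rdname tidy.mx_run_report
#' @export
glance.mx_run_report <- function(x, ...) {
  ok <- !x$distances$no_target_in_section
  tibble::tibble(
    n_sections = nrow(x$qc),
    n_cells_2d = sum(x$counts2d$n),
    n_cells_3d = sum(x$counts3d$n),
    mean_dsc = mean(x$qc$dsc),
    mean_adjacent_ncc = mean(x$adjacent$ncc, na.rm = TRUE),
    mean_d2d_um = if (any(ok)) mean(x$distances$d2d_um[ok]) else NA_real_,
    mean_d3d_um = if (any(ok)) mean(x$distances$d3d_um[ok]) else NA_real_,
    elapsed_s = x$elapsed_s)
}
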