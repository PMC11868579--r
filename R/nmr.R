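#' CPMG attenuation ratio
#'
#' Scales a with-protein (or post-competitor) signal intensity to the
#' protein-free reference intensity of the same fragment. Binding to the
#' protein shortens the small molecule's transverse relaxation and drives
#' the ratio below 1.
#'
#' @param i_signal Observed intensity (with protein, or after competitor).
#' @param i_ref Reference intensity without protein (> 0). Vectorised.
#' @return `i_signal / i_ref`.
#' @export
attenuation_ratio <- function(i_signal, i_ref) {
  if (any(!is.finite(i_ref)) || any(i_ref <= 0)) {
    stop("invalid reference intensity: i_ref must be finite and > 0",
         call. = FALSE)
  }
  if (any(!is.finite(i_signal)) || any(i_signal < 0)) {
    stop("signal intensities must be finite and >= 0", call. = FALSE)
  }
  i_signal / i_ref
}

#' Call fragment binders from a CPMG screening table
#'
#' A fragment is a binder when its attenuation ratio
#' `rho = i_protein / i_ref` falls at or below the threshold `tau`
#' (boundary counts as a hit). Binders with a post-competitor measurement
#' are classified by signal recovery: `site1_competed` when
#' `rho_comp - rho >= recovery_delta` (the competitor displaces the
#' fragment and the ratio recovers toward 1), otherwise `not_competed`;
#' binders without a competitor measurement and all non-binders are
#' `not_tested`.
#'
#' @param records Data frame with columns `fragment_id`, `cocktail_id`,
#'   `i_ref`, `i_protein` and optional `i_competitor` (`NA` = not tested).
#' @param tau Binder threshold on the attenuation ratio, in (0, 1)
#'   (default 0.8, i.e. at least 20 percent attenuation).
#' @param recovery_delta Minimum ratio recovery for a competed call
#'   (default 0.15).
#' @return A `hit_calls` list: `calls` (data frame `fragment_id`, `rho`,
#'   `rho_comp`, `is_binder`, `competition_class`) and `summary`
#'   (`n_library`, `n_hits`, `hit_rate_percent` rounded to 1 decimal).
#' @export
call_hits <- function(records, tau = 0.8, recovery_delta = 0.15) {
  if (NROW(records) == 0L) stop("records must be non-empty", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1) {
    stop("tau must lie in (0, 1)", call. = FALSE)
  }
  need <- c("fragment_id", "i_ref", "i_protein")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(records$fragment_id)) {
    dup <- records$fragment_id[duplicated(records$fragment_id)][1L]
    stop(sprintf("duplicate fragment_id '%s'", dup), call. = FALSE)
  }
  rho <- attenuation_ratio(records$i_protein, records$i_ref)
  icomp <- if ("i_competitor" %in% names(records)) records$i_competitor else
    rep(NA_real_, nrow(records))
  rho_comp <- rep(NA_real_, nrow(records))
  has_comp <- !is.na(icomp)
  if (any(has_comp)) {
    rho_comp[has_comp] <- attenuation_ratio(icomp[has_comp],
                                            records$i_ref[has_comp])
  }
  is_binder <- rho <= tau
  cls <- rep("not_tested", nrow(records))
  tested <- is_binder & has_comp
  cls[tested] <- ifelse(rho_comp[tested] - rho[tested] >= recovery_delta,
                        "site1_competed", "not_competed")
  calls <- data.frame(fragment_id = records$fragment_id, rho = rho,
                      rho_comp = rho_comp, is_binder = is_binder,
                      competition_class = cls, stringsAsFactors = FALSE)
  n_hits <- sum(is_binder)
  structure(list(
    calls = calls,
    summary = list(n_library = nrow(records), n_hits = n_hits,
                   hit_rate_percent = round(100 * n_hits / nrow(records), 1))
  ), class = "hit_calls")
}

#' Classify one binder's cap-site competition outcome
#'
#' @param call One-row data frame (or list) with `rho`, `rho_comp`,
#'   `is_binder` — a row of [call_hits()] output.
#' @param recovery_delta Minimum ratio recovery for a competed call.
#' @return `"site1_competed"`, `"not_competed"`, or `"not_tested"` when no
#'   competitor measurement exists.
#' @export
classify_competition <- function(call, recovery_delta = 0.15) {
  if (!isTRUE(as.logical(call$is_binder[1L]))) {
    stop("competition classification applies to binders only", call. = FALSE)
  }
  rho_comp <- call$rho_comp[1L]
  if (is.na(rho_comp)) {
    message("no competitor measurement; returning not_tested")
    return("not_tested")
  }
  if (rho_comp - call$rho[1L] >= recovery_delta) "site1_competed" else "not_competed"
}

#' @export
print.hit_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("hit_calls: %d/%d binders (%.1f%% hit rate); %d site1-competed\n",
              s$n_hits, s$n_library, s$hit_rate_percent,
              sum(x$calls$competition_class == "site1_competed")))
  invisible(x)
}

#' Read a CPMG screening table from CSV
#'
#' @param path CSV with columns `fragment_id`, `cocktail_id`, `i_ref`,
#'   `i_protein`, optional `i_competitor`.
#' @return Data frame suitable for [call_hits()].
#' @export
read_screen_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write hit calls and their summary
#'
#' @param hits A `hit_calls` object.
#' @param csv Path for the per-fragment calls CSV (`NULL` to skip).
#' @param json Path for the summary JSON (`NULL` to skip).
#' @return `hits`, invisibly.
#' @export
write_hit_calls <- function(hits, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(hits$calls, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(hits$summary, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(hits)
}
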