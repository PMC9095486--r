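# Modification stoichiometry and dose-response summaries from XIC areas.
#
# Both estimators assume equal ionization efficiency for the modified and
# unmodified species of a site, the standard working assumption when
# fragment pairs co-elute and differ by a small neutral group; the
# assumption is recorded in the output attributes.

check_xic <- function(t) {
  t <- tibble::as_tibble(t)
  needed <- c("site", "species", "condition", "replicate", "area")
  missing <- setdiff(needed, names(t))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "XIC table is missing column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  if (any(t$area < 0)) {
    rlang::abort("XIC areas must be non-negative.")
  }
  if (!all(t$species %in% c("modified", "unmodified"))) {
    rlang::abort("`species` must be 'modified' or 'unmodified'.")
  }
  t
}

#' Modification stoichiometry from XIC areas
#'
#' For each requested site and condition, the modified fraction is
#' area(modified) / (area(modified) + area(unmodified)) per replicate,
#' summarized as mean and sd over replicates. A replicate missing one
#' species row is treated as area 0 with a warning; a replicate whose total
#' area is 0 has an undefined fraction and is reported as missing.
#'
#' @param t An XIC table: columns `site`, `species`
#'   (`"modified"`/`"unmodified"`), `condition`, `replicate`, `area`.
#' @param sites,conditions Optional filters; default all.
#' @return A tibble with `site`, `condition`, `n_rep`, `fraction`
#'   (mean over replicates), `sd`, and `percent` (the fraction as a
#'   percentage, reported at 0.1% granularity in printed output).
#' @examples
#' t <- tibble::tibble(
#'   site = "U47", species = c("modified", "unmodified"),
#'   condition = "wt", replicate = 1, area = c(968, 32)
#' )
#' stoichiometry(t) # 96.8%
#' @export
stoichiometry <- function(t, sites = NULL, conditions = NULL) {
  t <- check_xic(t)
  if (!is.null(sites)) t <- dplyr::filter(t, .data$site %in% sites)
  if (!is.null(conditions)) {
    t <- dplyr::filter(t, .data$condition %in% conditions)
  }
  wide <- tidyr::pivot_wider(
    t,
    id_cols = c("site", "condition", "replicate"),
    names_from = "species", values_from = "area"
  )
  for (sp in c("modified", "unmodified")) {
    if (!sp %in% names(wide)) wide[[sp]] <- NA_real_
  }
  if (anyNA(wide$modified) || anyNA(wide$unmodified)) {
    rlang::warn("Missing species rows treated as area 0.")
    wide$modified[is.na(wide$modified)] <- 0
    wide$unmodified[is.na(wide$unmodified)] <- 0
  }
  total <- wide$modified + wide$unmodified
  wide$fraction <- ifelse(total > 0, wide$modified / total, NA_real_)
  out <- wide |>
    dplyr::group_by(.data$site, .data$condition) |>
    dplyr::summarise(
      n_rep = sum(!is.na(.data$fraction)),
      sd = stats::sd(.data$fraction, na.rm = TRUE),
      fraction = mean(.data$fraction, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fraction = ifelse(is.nan(.data$fraction), NA_real_, .data$fraction),
      percent = .data$fraction * 100
    ) |>
    dplyr::select(
      "site", "condition", "n_rep", "fraction", "sd", "percent"
    )
  attr(out, "assumes") <- "equal ionization efficiency of modified and unmodified species"
  out
}

#' Dose-response of modified fragments across ordered conditions
#'
#' Per condition, the (replicate-averaged) modified-species intensity of
#' each site is divided by that of a control site measured in the same
#' condition, and the ratio is then scaled so the first condition equals
#' 1.0. A per-site monotone-decrease flag reports whether the normalized
#' intensity strictly decreases along the condition order — the signature
#' of an eraser titration.
#'
#' @param t An XIC table (see [stoichiometry()]).
#' @param sites Sites to summarize (default: all but the control).
#' @param conditions Conditions in dose order; default: sorted unique.
#' @param control Site id of the normalization control fragment; must be
#'   present in every condition.
#' @return A tibble `site`, `condition`, `relative_intensity`, plus a
#'   per-site `monotone_decrease` flag (an attribute-free extra column).
#' @export
dose_response <- function(t, sites = NULL, conditions = NULL, control) {
  t <- check_xic(t)
  if (is.null(conditions)) conditions <- sort(unique(t$condition))
  mod <- t |>
    dplyr::filter(.data$species == "modified") |>
    dplyr::group_by(.data$site, .data$condition) |>
    dplyr::summarise(intensity = mean(.data$area), .groups = "drop")
  ctrl <- dplyr::filter(mod, .data$site == control)
  if (!all(conditions %in% ctrl$condition)) {
    rlang::abort(sprintf(
      "Control site '%s' is missing in some conditions.", control
    ))
  }
  if (is.null(sites)) sites <- setdiff(unique(mod$site), control)
  out <- mod |>
    dplyr::filter(.data$site %in% sites, .data$condition %in% conditions) |>
    dplyr::left_join(
      dplyr::select(ctrl, "condition", ctrl_intensity = "intensity"),
      by = "condition"
    ) |>
    dplyr::mutate(ratio = .data$intensity / .data$ctrl_intensity) |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(
      relative_intensity = .data$ratio /
        .data$ratio[match(conditions[1], .data$condition)]
    ) |>
    dplyr::arrange(match(.data$condition, conditions), .by_group = TRUE) |>
    dplyr::mutate(
      monotone_decrease = all(diff(.data$relative_intensity) < 0)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "site", "condition", "relative_intensity", "monotone_decrease"
    )
  out
}
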