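#' Published reference tables shipped with the package
#'
#' The package ships, verbatim, the published summary and fitted-parameter
#' tables of the Chinese-fir study it re-implements: field biomass summary
#' statistics by age group and train/test sample, the LiDAR-metric summary,
#' and the fitted parameters plus accuracy statistics of the four base
#' forms, the age-group dummy power models, and the additivity-constrained
#' SUR system. Values are stored exactly as printed, including rows with
#' apparent typographical defects, which carry a `typo_flag` (and, for the
#' biomass summary, an `additive_row` marker for rows whose component means
#' sum to the printed total mean). Nothing is silently corrected.
#'
#' Component labels in the SUR table follow the system-definition convention
#' (trunk row = the equation labelled Msg, bark = Msp, branch = Msz,
#' leaf = Msy). The published results section also prints the same
#' coefficients under swapped trunk/bark labels; the package keeps the
#' system-definition labelling throughout and flags the discrepancy in the
#' vignette rather than resolving it.
#'
#' @param table one of `"biomass_summary"`, `"lidar_summary"`,
#'   `"base_models"`, `"dummy_models"`, `"sur_models"`.
#' @return data.frame of the printed values.
#' @export
published_table <- function(table = c("biomass_summary", "lidar_summary",
                                      "base_models", "dummy_models",
                                      "sur_models")) {
  table <- match.arg(table)
  read.csv(published_table_path(table), stringsAsFactors = FALSE)
}

published_table_path <- function(table) {
  system.file("extdata", paste0(table, "_printed.csv"),
              package = "fircompat", mustWork = TRUE)
}

#' MD5 checksums of the shipped reference tables
#'
#' Used by the integrity test that guards the verbatim fixtures against
#' accidental edits.
#'
#' @return named character vector of MD5 hex digests.
#' @export
published_table_checksums <- function() {
  tabs <- c("biomass_summary", "lidar_summary", "base_models",
            "dummy_models", "sur_models")
  vapply(tabs, function(t) unname(tools::md5sum(published_table_path(t))),
         character(1))
}

#' Published fitted models as predictable objects
#'
#' Convenience constructors that turn the shipped parameter tables into fit
#' objects accepted by the package's `predict` methods: the published base
#' form for one component, the published dummy power model, or the full
#' published SUR system.
#'
#' @param form base model form (for `published_base_model`).
#' @param component biomass component: one of bark, trunk, branch, leaf,
#'   total (total is not available for the SUR system constructor, where it
#'   is the structural sum).
#' @return a `base_fit`, `dummy_fit` or `nsur_fit` object carrying the
#'   printed parameters (no data, no standard errors).
#' @export
published_base_model <- function(form, component) {
  tab <- published_table("base_models")
  row <- tab[tab$form == form & tab$component == component, ]
  if (nrow(row) != 1L)
    stop("no published base model for form=", form, ", component=", component,
         call. = FALSE)
  pn <- base_form_spec(form)$par_names
  base_model(form, setNames(as.numeric(row[1, pn]), pn), component)
}

#' @rdname published_base_model
#' @export
published_dummy_model <- function(component) {
  tab <- published_table("dummy_models")
  row <- tab[tab$component == component, ]
  if (nrow(row) != 1L)
    stop("no published dummy model for component=", component, call. = FALSE)
  dummy_model(scales = as.numeric(row[1, paste0("a", 1:5)]),
              b = row$b, c = row$c, component = component)
}

#' @rdname published_base_model
#' @export
published_sur_system <- function() {
  tab <- published_table("sur_models")
  tab <- tab[tab$component != "total", ]
  scales <- lapply(seq_len(nrow(tab)),
                   function(i) as.numeric(tab[i, paste0("s", 1:5)]))
  names(scales) <- tab$component
  exponents <- lapply(seq_len(nrow(tab)),
                      function(i) c(e = tab$e[i], f = tab$f[i]))
  names(exponents) <- tab$component
  nsur_system(scales, exponents)
}
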