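#' Aggregate specimen-level measurements to species values
#'
#' Species values are weighted averages of specimen-level measurements on the
#' raw (unlogged) scale, weighted by the number of specimens behind each row
#' where recorded (missing counts get weight 1). When the same specimen was
#' measured by several sources, only the most recently published source is kept
#' before averaging. The aggregated value is then log10-transformed, the scale
#' every downstream analysis uses.
#'
#' @param rows A data frame with columns `species`, `trait`, `value` (raw
#'   measurement), and optionally `n_specimens` (weight), `specimen_id` and
#'   `source_year` (for duplicate-specimen resolution).
#' @return A tibble with one row per species x trait: `value` (weighted mean,
#'   raw scale), `log10_value`, and `weight` (total weight).
#' @export
aggregate_specimens <- function(rows) {
  stopifnot(is.data.frame(rows))
  needed <- c("species", "trait", "value")
  if (!all(needed %in% names(rows))) {
    abort("specimen rows need columns species, trait, value")
  }
  tab <- as_tibble(rows)
  if (!"n_specimens" %in% names(tab)) tab$n_specimens <- NA_real_
  if (any(tab$value <= 0, na.rm = TRUE)) {
    abort("nonpositive raw measurement; values must be positive before logging")
  }
  if ("specimen_id" %in% names(tab) && "source_year" %in% names(tab)) {
    tab <- tab |>
      dplyr::group_by(.data$species, .data$trait, .data$specimen_id) |>
      dplyr::filter(is.na(.data$specimen_id) |
                      .data$source_year == max(.data$source_year)) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  tab |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::mutate(w = dplyr::coalesce(.data$n_specimens, 1)) |>
    dplyr::group_by(.data$species, .data$trait) |>
    dplyr::summarise(
      value = sum(.data$w * .data$value) / sum(.data$w),
      weight = sum(.data$w),
      .groups = "drop"
    ) |>
    dplyr::mutate(log10_value = log10(.data$value))
}

# numeric trait columns the loader recognises and log-transforms
trait_numeric_cols <- function() {
  c(paste0("mc", 1:5), paste0("pp", 1:5), "brain", "neocortex", "cerebellum")
}

trait_flag_cols <- function() {
  c("tool_any", "tool_true", "tool_manufacture",
    "tool_single_individual", "tool_captive_only", "is_hominin", "is_extant")
}

#' Load and validate a trait table from CSV
#'
#' Reads raw measurements (lengths in mm, brain mass in g, region volumes in
#' cm^3), validates that every present value is positive, and log10-transforms
#' all continuous traits. Endocranial volumes are accepted as brain mass at the
#' 1 g : 1 cm^3 conversion: a `brain_volume_cm3` column fills missing `brain`
#' values unchanged before logging. Tool-use indicator columns that are absent
#' default to `FALSE` for every species (species missing from the tool-use
#' compilation are assumed never observed using tools), as do the hominin flag
#' (default `FALSE`) and the extant flag (default `TRUE`).
#'
#' @param path CSV path. Must contain a `species` column; recognised trait
#'   columns are `mc1`-`mc5`, `pp1`-`pp5`, `brain` (g), `brain_volume_cm3`,
#'   `neocortex`, `cerebellum` (cm^3) and the logical flags `tool_any`,
#'   `tool_true`, `tool_manufacture`, `tool_single_individual`,
#'   `tool_captive_only`, `is_hominin`, `is_extant`.
#' @return A trait-table tibble on the log10 scale, species labels
#'   whitespace-normalised to match tree tip labels.
#' @export
load_trait_table <- function(path) {
  if (!file.exists(path)) abort(paste0("trait CSV not found: ", path))
  tab <- readr::read_csv(path, show_col_types = FALSE)
  if (!"species" %in% names(tab)) abort("trait CSV must have a 'species' column")
  tab$species <- gsub("[[:space:]]+", "_", trimws(tab$species))
  if (anyDuplicated(tab$species)) {
    abort(paste0("duplicate species in trait table: ",
                 paste(unique(tab$species[duplicated(tab$species)]), collapse = ", ")))
  }

  known <- c("species", trait_numeric_cols(), "brain_volume_cm3", trait_flag_cols())
  unknown <- setdiff(names(tab), known)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unrecognised columns: ", paste(unknown, collapse = ", ")))
  }

  if ("brain_volume_cm3" %in% names(tab)) {
    if (!"brain" %in% names(tab)) tab$brain <- NA_real_
    fill <- is.na(tab$brain) & !is.na(tab$brain_volume_cm3)
    tab$brain[fill] <- tab$brain_volume_cm3[fill]   # 1 g per cm^3
    tab$brain_volume_cm3 <- NULL
  }

  for (col in intersect(trait_numeric_cols(), names(tab))) {
    v <- tab[[col]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      abort(paste0("nonpositive value in column '", col, "' for species: ",
                   paste(tab$species[bad], collapse = ", ")))
    }
    tab[[col]] <- log10(v)
  }
  for (col in trait_flag_cols()) {
    if (!col %in% names(tab)) {
      tab[[col]] <- col == "is_extant"
    } else {
      tab[[col]] <- as.logical(tab[[col]])
      tab[[col]][is.na(tab[[col]])] <- col == "is_extant"
    }
  }
  if (any(tab$tool_true & !tab$tool_any) || any(tab$tool_manufacture & !tab$tool_any)) {
    abort("inconsistent tool flags: tool_true/tool_manufacture imply tool_any")
  }
  tab[, intersect(known, names(tab))]
}
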