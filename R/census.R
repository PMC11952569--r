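#' Conservation census of KZFP units across species
#'
#' Each KZFP unit (a distinct zinc-finger array identity, identified by its
#' cluster ID) is assigned, per carrier species, to exactly one conservation
#' category, evaluated in order: `unique_to_species` when no other species
#' carries it; `clade_shared` when at least one other species of the focal
#' clade carries it and no species outside the focal clade does;
#' `mammal_shared` when at least one mammal outside the focal clade carries
#' it and no non-mammal does; `beyond_mammals` otherwise. Under
#' `mode = "copies"` each unit is weighted by the species' copy count,
#' accounting for within-species duplications.
#'
#' @param units data.frame with columns `species`, `unit_id`, `copy_count`
#'   (integer >= 1); `(species, unit_id)` pairs must be unique.
#' @param clade_map data.frame with columns `species`, `clade`, `is_mammal`;
#'   every species in `units` must appear.
#' @param focal_clade The clade whose sharing is censused (e.g. rodents).
#' @param mode `"units"` (each unit counts once per carrier species) or
#'   `"copies"` (weighted by `copy_count`).
#' @return A data.frame with one row per species and columns `species`,
#'   `unique_to_species`, `clade_shared`, `mammal_shared`, `beyond_mammals`,
#'   `total`; the categories partition the total exactly. The result is
#'   invariant to the row order of `units`.
#' @export
census <- function(units, clade_map, focal_clade, mode = c("units", "copies")) {
  mode <- match.arg(mode)
  stopifnot(all(c("species", "unit_id", "copy_count") %in% names(units)),
            all(c("species", "clade", "is_mammal") %in% names(clade_map)))
  if (anyDuplicated(units[, c("species", "unit_id")])) {
    stop("(species, unit_id) pairs must be unique")
  }
  if (any(units$copy_count < 1)) stop("copy_count must be >= 1")
  missing <- setdiff(units$species, clade_map$species)
  if (length(missing) > 0) {
    stop("species missing from clade_map: ", paste(missing, collapse = ", "))
  }
  cm <- clade_map[!duplicated(clade_map$species), , drop = FALSE]
  rownames(cm) <- cm$species
  cats <- c("unique_to_species", "clade_shared", "mammal_shared",
            "beyond_mammals")
  species <- sort(unique(units$species))
  out <- matrix(0, nrow = length(species), ncol = length(cats),
                dimnames = list(species, cats))
  units <- units[order(units$unit_id, units$species), , drop = FALSE]
  for (uid in unique(units$unit_id)) {
    rows <- units[units$unit_id == uid, , drop = FALSE]
    carriers <- rows$species
    carrier_clades <- cm[carriers, "clade"]
    carrier_mammal <- cm[carriers, "is_mammal"]
    for (k in seq_len(nrow(rows))) {
      sp <- carriers[k]
      others <- carriers != sp
      cat <- if (!any(others)) {
        "unique_to_species"
      } else if (all(carrier_clades == focal_clade)) {
        "clade_shared"
      } else if (all(carrier_mammal)) {
        "mammal_shared"
      } else {
        "beyond_mammals"
      }
      w <- if (mode == "copies") rows$copy_count[k] else 1
      out[sp, cat] <- out[sp, cat] + w
    }
  }
  df <- data.frame(species = species, out, row.names = NULL,
                   stringsAsFactors = FALSE)
  df$total <- rowSums(out)
  df
}
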