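# Three-point trait scoring of the sensitivity axis (body mass, fossoriality,
# diurnality, habitat specialism) and the adaptive-capacity axis (dispersal,
# diet breadth, reproductive capacity, generation length), axis aggregation,
# quartile flagging, and the tercile break-shift robustness test.

#' Score a continuous trait on the three-point scale
#'
#' Tercile breaks are computed with the same engine as the climate terciles
#' ([tercile_breaks()]) and the resulting class 0/1/2 is mapped to a score by
#' direction: `"low_value_scores_2"` for traits where small values indicate
#' vulnerability (body mass, dispersal, diet breadth, reproductive capacity),
#' `"high_value_scores_2"` where large values do (generation length).
#'
#' @param values numeric vector across species (>= 3 distinct values).
#' @param direction `"low_value_scores_2"` or `"high_value_scores_2"`.
#' @param method tercile method, see [tercile_breaks()].
#' @param breaks optional externally supplied breaks (used by the break-shift
#'   test); when given, `method` is ignored.
#' @return integer scores in `{0, 1, 2}`.
#' @export
#' @examples
#' score_continuous(c(10, 100, 1000), "low_value_scores_2")   # 2 1 0
#' score_continuous(c(100, 1000, 10000), "high_value_scores_2")  # 0 1 2
score_continuous <- function(values,
                             direction = c("low_value_scores_2",
                                           "high_value_scores_2"),
                             method = "quantile", breaks = NULL) {
  direction <- match.arg(direction)
  if (is.null(breaks)) breaks <- tercile_breaks(values, method = method)
  cl <- classify_tercile(values, breaks)
  if (direction == "low_value_scores_2") 2L - cl else cl
}

#' Score habitat specialism from habitat breadth
#'
#' Species occupying five or more level-one habitat types score 0, two to
#' four types score 1, a single habitat type scores 2 (specialists are the
#' most sensitive).
#'
#' @param habitat_breadth integer count of level-one habitat types (>= 1).
#' @return integer scores in `{0, 1, 2}`.
#' @export
score_habitat <- function(habitat_breadth) {
  if (any(habitat_breadth < 1, na.rm = TRUE)) {
    stop("habitat breadth must be >= 1", call. = FALSE)
  }
  ifelse(habitat_breadth >= 5, 0L, ifelse(habitat_breadth >= 2, 1L, 2L))
}

#' Score a binary trait
#'
#' Binary traits take only the extreme scores 0 or 2. Fossoriality protects
#' (fossorial species can shelter from temperature extremes, score 0);
#' strict diurnality exposes (score 2).
#'
#' @param flag logical vector.
#' @param trait `"fossorial"` or `"diurnal_only"`.
#' @return integer scores in `{0, 2}`.
#' @export
#' @examples
#' score_binary(TRUE, "fossorial")     # 0
#' score_binary(TRUE, "diurnal_only")  # 2
score_binary <- function(flag, trait = c("fossorial", "diurnal_only")) {
  trait <- match.arg(trait)
  stopifnot(is.logical(flag))
  if (trait == "fossorial") ifelse(flag, 0L, 2L) else ifelse(flag, 2L, 0L)
}

#' Score migratory behavior as a dispersal proxy
#'
#' For species without dispersal-distance data (bats), migration class stands
#' in: sedentary (<10 km) scores 2, regional (10-100 km) scores 1,
#' long-distance (>100 km) scores 0.
#'
#' @param migration_class character vector with values `"sedentary"`,
#'   `"regional"`, `"long_distance"`.
#' @return integer scores in `{0, 1, 2}` (NA in, NA out).
#' @export
score_migration <- function(migration_class) {
  ok <- migration_class %in% c("sedentary", "regional", "long_distance")
  if (any(!ok & !is.na(migration_class))) {
    stop("unknown migration class: ",
         migration_class[!ok & !is.na(migration_class)][1], call. = FALSE)
  }
  unname(c(sedentary = 2L, regional = 1L, long_distance = 0L)[migration_class])
}

#' Reproductive capacity
#'
#' The number of offspring a mammal can maximally produce over its
#' reproductive life: `RC = (l_max - l_1r) * litter_size * litters_per_year`,
#' with `l_max` the maximum lifespan and `l_1r` the age at first reproduction
#' (both in years).
#'
#' @param l_max,l_1r,litter_size,litters_per_year numeric vectors.
#' @return numeric offspring counts.
#' @export
#' @examples
#' reproductive_capacity(10, 1, 4, 2)  # 72
reproductive_capacity <- function(l_max, l_1r, litter_size,
                                  litters_per_year) {
  if (any(l_max <= l_1r, na.rm = TRUE)) {
    stop("maximum lifespan must exceed age at first reproduction",
         call. = FALSE)
  }
  if (any(litter_size <= 0 | litters_per_year <= 0, na.rm = TRUE)) {
    stop("litter size and litters per year must be positive", call. = FALSE)
  }
  (l_max - l_1r) * litter_size * litters_per_year
}

#' Flag the top quartile of an axis
#'
#' Flags species at or above the 75th percentile of the rescaled axis values;
#' tied values share the flag, so the realized fraction may deviate from 25%.
#'
#' @param rescaled numeric axis values (>= 4 species, not all equal).
#' @return logical vector.
#' @export
flag_quartile <- function(rescaled) {
  if (length(rescaled) < 4) stop("need at least 4 species", call. = FALSE)
  if (length(unique(rescaled)) == 1) {
    stop("axis values are constant; quartile undefined", call. = FALSE)
  }
  rescaled >= stats::quantile(rescaled, 0.75, type = 7)
}

#' Score all traits and aggregate the two axes
#'
#' Applies the per-trait scorers to a trait table: continuous traits are
#' terciled across species (body mass, diet breadth, reproductive capacity
#' low -> 2; generation length high -> 2), habitat breadth uses the fixed
#' categorical thresholds, binary traits score 0/2. Dispersal uses the
#' continuous distance when present (terciled among species with distance
#' data, low -> 2) and the migration-class proxy otherwise; a species with
#' neither raises an error. Axis sums (4 traits each, 0-8) are rescaled
#' across species and the top sensitivity / lowest adaptive-capacity
#' quartiles flagged.
#'
#' @param traits data.frame as produced by [generate_traits()] (columns
#'   `species`, `body_mass_g`, `fossorial`, `diurnal_only`,
#'   `habitat_breadth`, `dispersal_km`, `migration_class`, `diet_breadth`,
#'   `l_max`, `l_1r`, `litter_size`, `litters_per_year`,
#'   `generation_length_d`).
#' @param tercile_method tercile method for continuous traits.
#' @return data.frame with per-trait scores (`s_bodymass`, `s_fossorial`,
#'   `s_diurnal`, `s_habitat`, `s_dispersal`, `s_diet`, `s_rc`,
#'   `s_genlength`), `sensitivity_sum`, `ac_sum`, `sensitivity_rescaled`,
#'   `ac_rescaled`, `high_sensitivity`, `low_adaptive_capacity`. The tercile
#'   method is recorded in attribute `"tercile_method"`.
#' @export
score_traits <- function(traits, tercile_method = "quantile") {
  no_disp <- is.na(traits$dispersal_km) & is.na(traits$migration_class)
  if (any(no_disp)) {
    stop(sprintf("species '%s' has neither dispersal distance nor migration class",
                 traits$species[no_disp][1]), call. = FALSE)
  }
  s_disp <- rep(NA_integer_, nrow(traits))
  has_km <- !is.na(traits$dispersal_km)
  if (any(has_km)) {
    s_disp[has_km] <- score_continuous(traits$dispersal_km[has_km],
                                       "low_value_scores_2",
                                       method = tercile_method)
  }
  s_disp[!has_km] <- score_migration(traits$migration_class[!has_km])

  rc <- reproductive_capacity(traits$l_max, traits$l_1r, traits$litter_size,
                              traits$litters_per_year)
  out <- data.frame(
    species = traits$species,
    s_bodymass = score_continuous(traits$body_mass_g, "low_value_scores_2",
                                  method = tercile_method),
    s_fossorial = score_binary(traits$fossorial, "fossorial"),
    s_diurnal = score_binary(traits$diurnal_only, "diurnal_only"),
    s_habitat = score_habitat(traits$habitat_breadth),
    s_dispersal = s_disp,
    s_diet = score_continuous(traits$diet_breadth, "low_value_scores_2",
                              method = tercile_method),
    s_rc = score_continuous(rc, "low_value_scores_2",
                            method = tercile_method),
    s_genlength = score_continuous(traits$generation_length_d,
                                   "high_value_scores_2",
                                   method = tercile_method))
  sens <- c("s_bodymass", "s_fossorial", "s_diurnal", "s_habitat")
  ac <- c("s_dispersal", "s_diet", "s_rc", "s_genlength")
  for (col in c(sens, ac)) {
    if (anyNA(out[[col]])) {
      stop(sprintf("species '%s' is missing score %s",
                   out$species[is.na(out[[col]])][1], col), call. = FALSE)
    }
  }
  out$sensitivity_sum <- rowSums(out[sens])
  out$ac_sum <- rowSums(out[ac])
  out$sensitivity_rescaled <- minmax_rescale(out$sensitivity_sum)
  out$ac_rescaled <- minmax_rescale(out$ac_sum)
  out$high_sensitivity <- flag_quartile(out$sensitivity_rescaled)
  out$low_adaptive_capacity <- flag_quartile(out$ac_rescaled)
  attr(out, "tercile_method") <- tercile_method
  out
}

#' Break-shift robustness test for a continuous trait
#'
#' Moves either the first or the second tercile break toward the minimum or
#' the maximum by 1%-33% of the value range (1% steps by default), re-scores
#' the trait with the shifted break, and reports the Pearson correlation
#' between the initial and scenario score vectors (scores treated as numeric
#' 0/1/2). A moved break is clamped at the other break so the class ordering
#' never inverts. Scenarios yielding a constant score vector get `r = NA`
#' with `constant = TRUE` rather than being dropped.
#'
#' @param values numeric trait values across species (>= 3 distinct).
#' @param direction score direction, see [score_continuous()].
#' @param shifts numeric vector of shift fractions of the value range.
#' @param method tercile method for the initial classification.
#' @param trait optional trait name carried into the output.
#' @return data.frame with columns `trait`, `which_break`, `direction`,
#'   `shift_fraction`, `pearson_r`, `constant`.
#' @export
break_shift_sensitivity <- function(values,
                                    direction = "low_value_scores_2",
                                    shifts = seq(0.01, 0.33, by = 0.01),
                                    method = "quantile",
                                    trait = NA_character_) {
  stopifnot(all(shifts >= 0), all(shifts <= 1))
  base_breaks <- tercile_breaks(values, method = method)
  initial <- score_continuous(values, direction, breaks = base_breaks)
  rng <- diff(range(values))
  grid <- expand.grid(which_break = c("first", "second"),
                      direction_shift = c("toward_min", "toward_max"),
                      shift_fraction = shifts,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- numeric(nrow(grid))
  constant <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    delta <- grid$shift_fraction[i] * rng
    if (grid$direction_shift[i] == "toward_min") delta <- -delta
    br <- base_breaks
    if (grid$which_break[i] == "first") {
      br[1] <- min(br[1] + delta, br[2])
    } else {
      br[2] <- max(br[2] + delta, br[1])
    }
    sc <- score_continuous(values, direction, breaks = br)
    if (length(unique(sc)) == 1 || length(unique(initial)) == 1) {
      r[i] <- NA_real_
      constant[i] <- TRUE
    } else {
      r[i] <- stats::cor(as.numeric(initial), as.numeric(sc))
    }
  }
  data.frame(trait = trait, which_break = grid$which_break,
             direction = grid$direction_shift,
             shift_fraction = grid$shift_fraction,
             pearson_r = r, constant = constant)
}
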