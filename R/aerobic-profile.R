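# Aerobic profile estimation from the Cooper 12-minute run test.
#
# All estimators take the Cooper distance K in meters. The quadratic
# VO2rel(K) has its positive root at ~431.93 m; distances at or below that
# give non-positive estimates and are rejected, as are implausible
# distances >= 6000 m.

.K_MIN <- 432
.K_MAX <- 6000

# lowest speed at which the affine speed map is invertible (m/s)
.V_INTERCEPT <- 0.1786

# kcal released per liter of oxygen consumed (caloric equivalent)
.KCAL_PER_L_O2 <- 5

.zone_levels <- c("below_elite", "elite", "top_elite", "world_class")

# Lower bounds (mL/kg/min) of the elite, top-elite and world-class bands:
# reference-group means minus one standard deviation (54.2-2.9, 60.6-4.8,
# 64.3-6.4).
.zone_thresholds <- c(elite = 51.3, top_elite = 55.8, world_class = 57.9)

.check_K <- function(K) {
  if (!is.numeric(K) || any(!is.finite(K))) {
    stop("Cooper distance `K` must be finite numeric (meters)", call. = FALSE)
  }
  if (any(K <= .K_MIN)) {
    stop("Cooper distance must exceed ", .K_MIN,
         " m (the VO2rel estimator is non-positive below its root at ~431.9 m)",
         call. = FALSE)
  }
  if (any(K >= .K_MAX)) {
    stop("Cooper distance must be below ", .K_MAX, " m", call. = FALSE)
  }
  invisible(K)
}

#' Relative maximal oxygen uptake from Cooper distance
#'
#' Estimates VO2rel (mL·kg^-1·min^-1) from the distance covered in the
#' Cooper 12-minute run test using the quadratic field estimator
#' \deqn{VO_{2rel} = 3.134304\times 10^{-7} K^2 + 0.02077344\, K - 9.03125,}
#' with `K` in meters. The estimator is strictly increasing on its valid
#' domain (432 m, 6000 m).
#'
#' @param K Cooper 12-minute run distance in meters (vectorized).
#' @return Estimated VO2rel in mL·kg^-1·min^-1.
#' @seealso [vo2max_absolute()], [velocity_at_vo2max()], [aerobic_profile()]
#' @examples
#' vo2rel_from_distance(2750) # 50.47, i.e. 50.5 at 1 decimal
#' @export
vo2rel_from_distance <- function(K) {
  .check_K(K)
  3.134304e-7 * K^2 + 0.02077344 * K - 9.03125
}

#' Absolute maximal oxygen uptake
#'
#' Scales [vo2rel_from_distance()] by body weight: VO2max (L·min^-1) =
#' VO2rel × BW / 1000.
#'
#' @param K Cooper distance in meters.
#' @param weight Body weight in kg; must be positive.
#' @return VO2max in L·min^-1.
#' @examples
#' vo2max_absolute(2750, 73) # 3.68
#' @export
vo2max_absolute <- function(K, weight) {
  if (!is.numeric(weight) || any(!is.finite(weight)) || any(weight <= 0)) {
    stop("`weight` must be positive (kg)", call. = FALSE)
  }
  vo2rel_from_distance(K) * weight / 1000
}

#' Maximal aerobic speed (velocity at VO2max)
#'
#' Affine map from Cooper distance to the lowest running speed eliciting
#' VO2max (vVO2max, also called MAS): `v = 0.0014 K + 0.1786` m·s^-1.
#' Because the map is affine, it commutes with averaging: the mean of
#' predicted speeds equals the speed predicted at the mean distance.
#'
#' @inheritParams vo2rel_from_distance
#' @return vVO2max in m·s^-1.
#' @examples
#' velocity_at_vo2max(2324) # 3.43
#' @export
velocity_at_vo2max <- function(K) {
  .check_K(K)
  0.0014 * K + .V_INTERCEPT
}

#' Cooper distance equivalent of a running speed
#'
#' Inverse of [velocity_at_vo2max()]: the Cooper distance whose predicted
#' maximal aerobic speed equals `v`. Used to map a training speed back onto
#' the distance scale so its oxygen cost can be read off the VO2rel curve.
#'
#' @param v Running speed in m·s^-1; must exceed 0.1786 (the intercept of
#'   the speed map).
#' @return Distance in meters.
#' @export
distance_from_velocity <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)) || any(v <= .V_INTERCEPT)) {
    stop("speed must exceed ", .V_INTERCEPT, " m/s to be invertible",
         call. = FALSE)
  }
  (v - .V_INTERCEPT) / 0.0014
}

#' Running (muscle) efficiency
#'
#' Ratio of the mechanical output proxy (maximal aerobic speed) to the
#' metabolic power proxy (VO2max converted at 5 kcal per liter of O2),
#' expressed as a percentage:
#' \deqn{\eta = 100 \cdot vVO_{2max} / (5 \cdot VO_{2max}).}
#'
#' @param v_vo2max Maximal aerobic speed, m·s^-1.
#' @param vo2max Absolute maximal oxygen uptake, L·min^-1; must be positive.
#' @return Efficiency in percent.
#' @examples
#' muscle_efficiency(3.65, 2.81) # 25.98
#' @export
muscle_efficiency <- function(v_vo2max, vo2max) {
  if (!is.numeric(vo2max) || any(!is.finite(vo2max)) || any(vo2max <= 0)) {
    stop("`vo2max` must be positive (L/min)", call. = FALSE)
  }
  100 * v_vo2max / (.KCAL_PER_L_O2 * vo2max)
}

#' Fraction of VO2max elicited at a fraction of maximal aerobic speed
#'
#' For an athlete whose Cooper distance is `K`, running at `p` × vVO2max,
#' the elicited oxygen uptake as a fraction of VO2max is obtained by
#' composing the three field estimators: map the training speed back to its
#' Cooper-distance equivalent, evaluate the VO2rel curve there, and divide
#' by VO2rel at `K`. Because the VO2rel curve is convex increasing while the
#' speed map is affine, the resulting fraction is below `p` for `p < 1` and
#' equals 1 at `p = 1`.
#'
#' @param K Cooper distance in meters.
#' @param p Fraction of vVO2max in (0, 1].
#' @return Fraction of VO2max in (0, 1].
#' @examples
#' vo2_fraction_at_speed(2324, 0.85) # ~0.801
#' @export
vo2_fraction_at_speed <- function(K, p) {
  .check_K(K)
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("`p` must be a fraction of vVO2max in (0, 1]", call. = FALSE)
  }
  v <- p * velocity_at_vo2max(K)
  vo2rel_from_distance(distance_from_velocity(v)) / vo2rel_from_distance(K)
}

#' Performance zone from relative VO2max
#'
#' Classifies VO2rel into the aerobic performance bands of elite women's
#' team handball: world-class (>= 57.9), top-elite (>= 55.8), elite
#' (>= 51.3), otherwise below-elite (mL·kg^-1·min^-1). Thresholds are the
#' reference-group means minus one standard deviation; boundaries are
#' inclusive.
#'
#' @param vo2rel Relative VO2max in mL·kg^-1·min^-1 (vectorized).
#' @return Ordered factor with levels below_elite < elite < top_elite <
#'   world_class.
#' @examples
#' classify_zone(c(50.48, 51.3, 58.0))
#' @export
classify_zone <- function(vo2rel) {
  if (!is.numeric(vo2rel) || any(!is.finite(vo2rel)) || any(vo2rel <= 0)) {
    stop("`vo2rel` must be positive", call. = FALSE)
  }
  idx <- 1L +
    (vo2rel >= .zone_thresholds[["elite"]]) +
    (vo2rel >= .zone_thresholds[["top_elite"]]) +
    (vo2rel >= .zone_thresholds[["world_class"]])
  factor(.zone_levels[idx], levels = .zone_levels, ordered = TRUE)
}

#' Full aerobic profile from a Cooper result
#'
#' Composes the four field estimators into one record: VO2rel, absolute
#' VO2max, maximal aerobic speed, running efficiency, and the performance
#' zone implied by VO2rel.
#'
#' @param K Cooper distance in meters (vectorized).
#' @param weight Body weight in kg (recycled against `K`).
#' @return A data.frame with columns `distance_m`, `weight_kg`, `vo2rel`,
#'   `vo2max`, `v_vo2max`, `efficiency`, `zone`.
#' @examples
#' aerobic_profile(2750, 73)
#' @export
aerobic_profile <- function(K, weight) {
  vo2rel <- vo2rel_from_distance(K)
  vo2max <- vo2max_absolute(K, weight)
  v <- velocity_at_vo2max(K)
  data.frame(
    distance_m = K,
    weight_kg = weight,
    vo2rel = vo2rel,
    vo2max = vo2max,
    v_vo2max = v,
    efficiency = muscle_efficiency(v, vo2max),
    zone = classify_zone(vo2rel)
  )
}

#' Aerobic profile for an athlete record and a Cooper test result
#'
#' Record-level wrapper around [aerobic_profile()] that carries athlete id
#' and timepoint through. `athlete` needs a `weight_kg` field (and `id`);
#' `result` needs `distance_m` (and `id`, `timepoint`). If both carry an
#' `id`, they must agree.
#'
#' @param athlete A list or one-row data.frame with at least `weight_kg`.
#' @param result A list or one-row data.frame with at least `distance_m`.
#' @return One-row data.frame: id, timepoint, plus the profile columns.
#' @export
profile_from_cooper <- function(athlete, result) {
  athlete <- as.list(athlete)
  result <- as.list(result)
  if (is.null(athlete$weight_kg)) {
    stop("`athlete` must have a `weight_kg` field", call. = FALSE)
  }
  if (is.null(result$distance_m)) {
    stop("`result` must have a `distance_m` field", call. = FALSE)
  }
  if (!is.null(athlete$id) && !is.null(result$id) &&
      !identical(as.character(athlete$id), as.character(result$id))) {
    stop("athlete and Cooper result ids differ", call. = FALSE)
  }
  prof <- aerobic_profile(result$distance_m, athlete$weight_kg)
  cbind(
    data.frame(
      id = if (is.null(athlete$id)) NA_character_ else as.character(athlete$id),
      timepoint = if (is.null(result$timepoint)) NA_integer_
                  else as.integer(result$timepoint)
    ),
    prof
  )
}

#' Profiles for a cohort of athletes across timepoints
#'
#' Joins an athlete table to a long Cooper-result table by `id` and computes
#' one aerobic profile per (id, timepoint).
#'
#' @param athletes data.frame with columns `id`, `weight_kg` (extra columns
#'   such as `age`, `height_cm` are allowed and ignored).
#' @param cooper data.frame with columns `id`, `timepoint`, `distance_m`.
#' @return data.frame with one row per (id, timepoint), ordered by id then
#'   timepoint, containing all profile columns.
#' @export
cooper_profiles <- function(athletes, cooper) {
  validate_athletes(athletes)
  validate_cooper(cooper)
  if (!all(cooper$id %in% athletes$id)) {
    missing <- setdiff(unique(cooper$id), athletes$id)
    stop("Cooper results for unknown athlete id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  w <- athletes$weight_kg[match(cooper$id, athletes$id)]
  prof <- aerobic_profile(cooper$distance_m, w)
  out <- cbind(
    data.frame(id = as.character(cooper$id),
               timepoint = as.integer(cooper$timepoint)),
    prof
  )
  out[order(out$id, out$timepoint), , drop = FALSE]
}
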