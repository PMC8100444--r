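#' Parameters of the synthetic tripod gait
#'
#' The generator stands in for motion-capture joint-angle recordings of a
#' straight-walking stick insect. Legs oscillate periodically with a tripod
#' phase structure: \{L1, R2, L3\} share one phase and \{R1, L2, R3\} walk in
#' antiphase. Within a cycle each leg spends `duty` of the period in stance
#' (protraction-retraction angle alpha ramping rearward, tarsus down) and
#' the rest in a faster swing return with the femur levated and the tibia
#' flexed.
#'
#' @param period step-cycle length in frames (>= 2).
#' @param duty stance fraction of the cycle, in (0, 1).
#' @param frame_rate frames per second (metadata only).
#' @param phases named per-leg phase offsets in fractions of a period,
#'   in `[0, 1)`.
#' @param alpha_amp half-amplitude of the alpha oscillation (rad).
#' @param alpha_mid per-pair alpha midpoints (rad): front legs aimed
#'   forward, hind legs rearward.
#' @param beta_stance femur elevation during stance (rad).
#' @param swing_lift additional levation at mid-swing (rad).
#' @param gamma_stance femur-tibia interior angle during stance (rad).
#' @param swing_flex additional flexion (reduction of gamma) at mid-swing (rad).
#' @param jitter_sd standard deviation of optional Gaussian angle jitter
#'   (rad, default 0 = noise free).
#' @param seed integer seed for the jitter.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(period = 40, duty = 0.75, frame_rate = 50,
                        phases = c(L1 = 0, R2 = 0, L3 = 0,
                                   R1 = 0.5, L2 = 0.5, R3 = 0.5),
                        alpha_amp = 0.35,
                        alpha_mid = c(0.45, 0, -0.45),
                        beta_stance = 0.25,
                        swing_lift = 0.35,
                        gamma_stance = 1.8,
                        swing_flex = 0.4,
                        jitter_sd = 0,
                        seed = 1L) {
  p <- structure(list(period = period, duty = duty, frame_rate = frame_rate,
                      phases = phases, alpha_amp = alpha_amp,
                      alpha_mid = alpha_mid, beta_stance = beta_stance,
                      swing_lift = swing_lift, gamma_stance = gamma_stance,
                      swing_flex = swing_flex, jitter_sd = jitter_sd,
                      seed = as.integer(seed)),
                 class = "gait_params")
  if (!is.numeric(p$period) || p$period < 2)
    rlang::abort("period must be at least 2 frames")
  if (p$duty <= 0 || p$duty >= 1)
    rlang::abort("duty cycle must lie strictly between 0 and 1")
  if (!setequal(names(p$phases), leg_ids()))
    rlang::abort("phases must name all six legs L1-L3, R1-R3")
  if (any(p$phases < 0 | p$phases >= 1))
    rlang::abort("phase offsets must lie in [0, 1)")
  if (length(p$alpha_mid) != 3L)
    rlang::abort("alpha_mid needs one midpoint per leg pair")
  if (p$jitter_sd < 0) rlang::abort("jitter_sd must be non-negative")
  p
}

# Evaluate the piecewise waveform at cycle phase phi in [0, 1).
gait_waveform <- function(phi, pair, p) {
  stance <- phi < p$duty
  u <- ifelse(stance, phi / p$duty, (phi - p$duty) / (1 - p$duty))
  alpha <- ifelse(stance,
                  p$alpha_mid[pair] + p$alpha_amp * (1 - 2 * u),
                  p$alpha_mid[pair] - p$alpha_amp * cos(pi * u))
  beta <- ifelse(stance, p$beta_stance,
                 p$beta_stance + p$swing_lift * sin(pi * u))
  gamma <- ifelse(stance, p$gamma_stance,
                  p$gamma_stance - p$swing_flex * sin(pi * u))
  list(alpha = alpha, beta = beta, gamma = gamma)
}

#' Generate a joint-angle trajectory with tripod-gait structure
#'
#' @param n_frames number of frames (>= 0).
#' @param params a [gait_params()].
#' @return A tibble with a `frame` column and one column per joint degree
#'   of freedom (see [angle_names()]), one row per frame; attributes
#'   `frame_rate` and `source = "synthetic"`. Deterministic for a fixed
#'   seed.
#' @export
generate_gait <- function(n_frames, params = gait_params()) {
  stopifnot(inherits(params, "gait_params"))
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 0)
    rlang::abort("n_frames must be a single non-negative count")
  n_frames <- as.integer(n_frames)
  cols <- setNames(vector("list", length(angle_names())), angle_names())
  t <- seq_len(n_frames) - 1L
  for (leg in leg_ids()) {
    pair <- as.integer(substr(leg, 2, 2))
    phi <- ((t / params$period) + params$phases[[leg]]) %% 1
    w <- gait_waveform(phi, pair, params)
    cols[[paste0(leg, "_alpha")]] <- w$alpha
    cols[[paste0(leg, "_beta")]] <- w$beta
    cols[[paste0(leg, "_gamma")]] <- w$gamma
  }
  cols[["head_pitch"]] <- rep(0, n_frames)
  cols[["head_yaw"]] <- rep(0, n_frames)
  out <- tibble::as_tibble(c(list(frame = seq_len(n_frames)), cols))
  if (params$jitter_sd > 0 && n_frames > 0) {
    jit <- with_local_seed(params$seed, {
      matrix(rnorm(n_frames * length(angle_names()), sd = params$jitter_sd),
             nrow = n_frames)
    })
    out[angle_names()] <- out[angle_names()] + jit
  }
  attr(out, "frame_rate") <- params$frame_rate
  attr(out, "source") <- "synthetic"
  out
}

# Run expr under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a joint-angle trajectory to delimited text
#'
#' The on-disk dialect is a CSV with one row per frame, one column per
#' degree of freedom, preceded by comment lines carrying the frame rate
#' and the angular units.
#'
#' @param trajectory a trajectory tibble as from [generate_gait()].
#' @param path output file.
#' @param units `"rad"` (default) or `"deg"`.
#' @return `path`, invisibly.
#' @export
write_joint_angles <- function(trajectory, path, units = c("rad", "deg")) {
  units <- match.arg(units)
  out <- trajectory
  if (units == "deg")
    out[angle_names()] <- out[angle_names()] * 180 / pi
  fr <- attr(trajectory, "frame_rate")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# frame_rate: ", if (is.null(fr)) 50 else fr),
               paste0("# units: ", units)), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a joint-angle trajectory from delimited text
#'
#' Accepts the dialect written by [write_joint_angles()]: leading `#`
#' comment lines may declare `frame_rate` and `units` (`deg` or `rad`;
#' degrees are converted to radians). All 18 leg angle columns are
#' required; head angles default to 0; unknown extra columns are ignored
#' with a message.
#'
#' @param path input file.
#' @return A trajectory tibble like [generate_gait()]'s, with
#'   `source = "file"`.
#' @export
read_joint_angles <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "#")]
  get_meta <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (!length(m)) return(default)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  frame_rate <- as.numeric(get_meta("frame_rate", "50"))
  units <- get_meta("units", "rad")
  if (!units %in% c("rad", "deg"))
    rlang::abort(paste0("unknown units declaration: ", units))
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  required <- setdiff(angle_names(), c("head_pitch", "head_yaw"))
  missing <- setdiff(required, names(df))
  if (length(missing))
    rlang::abort(paste0("missing joint-angle column(s): ",
                        paste(missing, collapse = ", ")))
  extra <- setdiff(names(df), c("frame", angle_names()))
  if (length(extra))
    message("ignoring unmapped column(s): ", paste(extra, collapse = ", "))
  known <- intersect(names(df), angle_names())
  for (cn in known) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      rlang::abort(paste0("non-numeric value in column ", cn,
                          ", row ", bad))
    }
  }
  n <- nrow(df)
  out <- tibble::tibble(frame = seq_len(n))
  for (cn in angle_names()) {
    v <- if (cn %in% names(df)) df[[cn]]
         else if (cn == "head_pitch" || cn == "head_yaw") rep(0, n)
    out[[cn]] <- v
  }
  if (units == "deg")
    out[angle_names()] <- out[angle_names()] * pi / 180
  attr(out, "frame_rate") <- frame_rate
  attr(out, "source") <- "file"
  out
}
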