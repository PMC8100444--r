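#' Body geometry of the stick-insect model
#'
#' Defines the kinematic chain of a *Carausius morosus*-like stick insect as
#' cylinder/sphere primitives: five trunk segments (head, pro-, meso-,
#' metathorax, abdomen) plus six legs with a lumped coxa+trochanter, femur,
#' tibia and tarsus each. All lengths are in millimetres in the body frame
#' (x anterior, y left, z up, animal centred at the origin, ground at z = 0).
#' Defaults approximate an adult female with a total body length of about
#' 80 mm; radii and shading are model choices, not measured values.
#'
#' @param trunk named numeric vector of trunk segment lengths (mm), names
#'   `head`, `prothorax`, `mesothorax`, `metathorax`, `abdomen`.
#' @param legs data frame with one row per leg pair (`pair` = 1 front, 2
#'   middle, 3 hind) and columns `coxa`, `femur`, `tibia`, `tarsus` (mm).
#' @param attachments data frame with one row per pair: `segment` (thorax
#'   segment carrying the pair), `along` (mm from the segment's anterior
#'   end) and `lateral` (mm, absolute offset from the midline; left and
#'   right legs mirror it).
#' @param height height of the trunk axis above the ground plane (mm).
#' @param trunk_radii,leg_radii named cylinder radii (mm).
#' @param sphere_radii named joint-sphere radii (mm): `trunk`, `attach`,
#'   `CxTr`, `FeTi`, `TiTa`, `tip`.
#' @param trunk_landmarks named character vector choosing which 4 trunk/head
#'   stations are tracked landmarks; names become landmark labels, values
#'   are station keys among `head_ant`, `head_post`, `pro_post`,
#'   `meso_post`, `meta_post`, `abd_post`.
#' @param scale global scale factor already applied (bookkeeping; use
#'   [scale_geometry()] to rescale).
#'
#' @return An object of class `body_geometry`.
#' @seealso [scale_geometry()], [forward_kinematics()], [landmark_names()]
#' @export
body_geometry <- function(trunk = c(head = 6, prothorax = 8, mesothorax = 18,
                                    metathorax = 16, abdomen = 32),
                          legs = tibble::tibble(
                            pair = 1:3,
                            coxa = c(4, 4, 4),
                            femur = c(14, 11, 13),
                            tibia = c(14, 10, 13),
                            tarsus = c(7, 6, 7)),
                          attachments = tibble::tibble(
                            pair = 1:3,
                            segment = c("prothorax", "mesothorax", "metathorax"),
                            along = c(6, 16, 14),
                            lateral = c(2.5, 2.5, 2.5)),
                          height = 12,
                          trunk_radii = c(head = 2.2, prothorax = 2.0,
                                          mesothorax = 2.0, metathorax = 2.0,
                                          abdomen = 1.8),
                          leg_radii = c(coxa = 1.0, femur = 0.8,
                                        tibia = 0.6, tarsus = 0.45),
                          sphere_radii = c(trunk = 2.1, attach = 1.2,
                                           CxTr = 1.0, FeTi = 0.85,
                                           TiTa = 0.7, tip = 0.55),
                          trunk_landmarks = c(Head = "head_ant",
                                              ProMeso = "pro_post",
                                              MesoMeta = "meso_post",
                                              MetaAbd = "meta_post"),
                          scale = 1.0) {
  g <- structure(
    list(trunk = trunk, legs = tibble::as_tibble(legs),
         attachments = tibble::as_tibble(attachments), height = height,
         trunk_radii = trunk_radii, leg_radii = leg_radii,
         sphere_radii = sphere_radii, trunk_landmarks = trunk_landmarks,
         scale = scale),
    class = "body_geometry")
  validate_geometry(g)
  g
}

#' Default stick-insect geometry
#'
#' @return A `body_geometry` with the package defaults (total body length
#'   80 mm, six legs, mirror-symmetric attachments).
#' @export
default_geometry <- function() body_geometry()

validate_geometry <- function(g) {
  segs <- c("head", "prothorax", "mesothorax", "metathorax", "abdomen")
  if (!setequal(names(g$trunk), segs) || any(g$trunk <= 0))
    rlang::abort("trunk must name all five segments with positive lengths")
  if (nrow(g$legs) != 3L ||
      any(as.matrix(g$legs[, c("coxa", "femur", "tibia", "tarsus")]) < 0))
    rlang::abort("legs must give non-negative segment lengths for pairs 1:3")
  if (any(g$legs$femur <= 0))
    rlang::abort("femur lengths must be positive")
  if (any(unlist(g$trunk_radii) <= 0) || any(unlist(g$leg_radii) <= 0) ||
      any(unlist(g$sphere_radii) <= 0))
    rlang::abort("all radii must be positive")
  if (g$height <= 0) rlang::abort("trunk height must be positive")
  if (g$scale <= 0) rlang::abort("scale must be positive")
  if (length(g$trunk_landmarks) != 4L)
    rlang::abort("trunk_landmarks must select exactly 4 stations")
  ok <- g$trunk_landmarks %in% names(trunk_stations(g))
  if (!all(ok))
    rlang::abort(paste0("unknown trunk station: ",
                        paste(g$trunk_landmarks[!ok], collapse = ", ")))
  invisible(g)
}

#' @export
print.body_geometry <- function(x, ...) {
  cat("<body_geometry>\n")
  cat("  total body length:", sum(x$trunk), "mm (scale", x$scale, ")\n")
  cat("  trunk:", paste(names(x$trunk), x$trunk, sep = "=", collapse = ", "), "\n")
  cat("  legs: 6 (3 mirror-symmetric pairs), height", x$height, "mm\n")
  invisible(x)
}

# Trunk station x-coordinates (body frame, animal centred at origin).
trunk_stations <- function(g) {
  L <- sum(g$trunk)
  tip <- L / 2
  c(head_ant = tip,
    head_post = tip - g$trunk[["head"]],
    pro_post = tip - g$trunk[["head"]] - g$trunk[["prothorax"]],
    meso_post = tip - g$trunk[["head"]] - g$trunk[["prothorax"]] -
      g$trunk[["mesothorax"]],
    meta_post = tip - g$trunk[["head"]] - g$trunk[["prothorax"]] -
      g$trunk[["mesothorax"]] - g$trunk[["metathorax"]],
    abd_post = -tip)
}

#' Rescale a body geometry
#'
#' Multiplies every segment length, attachment offset, trunk height and
#' radius by `s` and records the factor. Radii scale with the body so that
#' the rendered animal keeps its proportions at any size.
#'
#' @param geometry a [body_geometry()].
#' @param s positive scale factor.
#' @return The rescaled `body_geometry`.
#' @export
scale_geometry <- function(geometry, s) {
  stopifnot(inherits(geometry, "body_geometry"))
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    rlang::abort("scale factor must be a single positive number")
  g <- geometry
  g$trunk <- g$trunk * s
  g$legs[c("coxa", "femur", "tibia", "tarsus")] <-
    g$legs[c("coxa", "femur", "tibia", "tarsus")] * s
  g$attachments[c("along", "lateral")] <- g$attachments[c("along", "lateral")] * s
  g$height <- g$height * s
  g$trunk_radii <- g$trunk_radii * s
  g$leg_radii <- g$leg_radii * s
  g$sphere_radii <- g$sphere_radii * s
  g$scale <- g$scale * s
  g
}

#' Landmark labels in canonical order
#'
#' The 22 tracked body features: the coxa-trochanter (CxTr), femur-tibia
#' (FeTi) and tibia-tarsus (TiTa) joints of all six legs (R1-R3 then
#' L1-L3), followed by 4 trunk/head stations. The order is stable and is
#' the column order of every annotation table the package writes.
#'
#' @param geometry optional [body_geometry()]; its `trunk_landmarks` names
#'   supply the 4 trunk labels. Defaults to the package default choice.
#' @return Character vector of length 22.
#' @export
landmark_names <- function(geometry = NULL) {
  trunk <- if (is.null(geometry)) {
    c("Head", "ProMeso", "MesoMeta", "MetaAbd")
  } else {
    names(geometry$trunk_landmarks)
  }
  legs <- paste(rep(c("R1", "R2", "R3", "L1", "L2", "L3"), each = 3),
                c("CxTr", "FeTi", "TiTa"))
  c(legs, trunk)
}

leg_ids <- function() c("R1", "R2", "R3", "L1", "L2", "L3")

#' Joint-angle set for one frame
#'
#' Builds the named angle vector the forward-kinematics chain consumes:
#' per leg a protraction(+)/retraction(-) angle `alpha` about the vertical
#' axis at the coxa, a levation(+)/depression(-) angle `beta` about the
#' horizontal leg axis, and the femur-tibia interior angle `gamma`
#' (`gamma = pi` is a straight leg). Optional head `pitch`/`yaw`. All
#' radians; unspecified angles default to the reference posture
#' (`alpha = 0`, `beta = 0`, `gamma = pi`, head level).
#'
#' @param ... named angles such as `R1_alpha = 0.2`, `head_yaw = 0.1`.
#' @return Named numeric vector over the full degree-of-freedom set.
#' @export
joint_angles <- function(...) {
  a <- setNames(rep(0, length(angle_names())), angle_names())
  a[grepl("_gamma$", names(a))] <- pi
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(a))
    if (length(bad))
      rlang::abort(paste0("unknown joint angle(s): ", paste(bad, collapse = ", ")))
    a[names(dots)] <- dots
  }
  a
}

#' Names of all joint degrees of freedom
#' @return Character vector: 18 leg angles plus `head_pitch`, `head_yaw`.
#' @export
angle_names <- function() {
  c(as.vector(t(outer(leg_ids(), c("alpha", "beta", "gamma"), paste, sep = "_"))),
    "head_pitch", "head_yaw")
}

# Coerce a one-row data frame or named vector onto the full DOF set.
as_joint_angles <- function(angles) {
  if (is.data.frame(angles)) {
    stopifnot(nrow(angles) == 1L)
    angles <- unlist(angles[intersect(names(angles), angle_names())])
  }
  if (is.null(names(angles)))
    rlang::abort("joint angles must be named")
  if (!all(is.finite(angles)))
    rlang::abort(paste0("non-finite joint angle: ",
                        paste(names(angles)[!is.finite(angles)], collapse = ", ")))
  joint_angles(angles[intersect(names(angles), angle_names())])
}

#' Forward kinematics: joint angles to a 3D posture
#'
#' Computes the 22 landmark positions and the cylinder/sphere render
#' primitives for one frame. Each leg is a serial chain from its thorax
#' attachment: the lumped coxa+trochanter swings horizontally by `alpha`,
#' the femur leaves the coxa-trochanter joint at elevation `beta`, and the
#' tibia continues at the interior femur-tibia angle `gamma`, all within
#' the vertical plane selected by `alpha`. Distances between consecutive
#' landmarks equal the (scaled) segment lengths exactly.
#'
#' @param angles output of [joint_angles()] (or a one-row data frame of
#'   angle columns, e.g. one row of [generate_gait()]).
#' @param geometry a [body_geometry()].
#' @return An object of class `posture3d`: list with `landmarks` (tibble
#'   `landmark`, `x`, `y`, `z`), `primitives` (tibble of cylinders and
#'   spheres with a `part` label) and the geometry's `scale`.
#' @export
forward_kinematics <- function(angles, geometry = default_geometry()) {
  stopifnot(inherits(geometry, "body_geometry"))
  a <- as_joint_angles(angles)
  st <- trunk_stations(geometry)
  h <- geometry$height

  # trunk axis points (head handled separately for pitch/yaw)
  head_post <- c(st[["head_post"]], 0, h)
  cp <- cos(a[["head_pitch"]]); sp <- sin(a[["head_pitch"]])
  cy <- cos(a[["head_yaw"]]);   sy <- sin(a[["head_yaw"]])
  head_dir <- c(cy * cp, sy * cp, sp)
  head_ant <- head_post + geometry$trunk[["head"]] * head_dir

  station_pts <- list(
    head_ant = head_ant,
    head_post = head_post,
    pro_post = c(st[["pro_post"]], 0, h),
    meso_post = c(st[["meso_post"]], 0, h),
    meta_post = c(st[["meta_post"]], 0, h),
    abd_post = c(st[["abd_post"]], 0, h))

  prim <- list()
  parts <- character(0)
  push <- function(type, p1, p2, r, part) {
    prim[[length(prim) + 1L]] <<- c(type, p1, p2, r)
    parts <<- c(parts, part)
  }

  # trunk cylinders + boundary spheres
  seg_ends <- list(head = c("head_post", "head_ant"),
                   prothorax = c("pro_post", "head_post"),
                   mesothorax = c("meso_post", "pro_post"),
                   metathorax = c("meta_post", "meso_post"))
  for (sg in names(seg_ends)) {
    e <- seg_ends[[sg]]
    push(1, station_pts[[e[1]]], station_pts[[e[2]]],
         geometry$trunk_radii[[sg]], paste0("trunk_", sg))
  }
  for (stn in c("head_ant", "head_post", "pro_post", "meso_post", "meta_post"))
    push(0, station_pts[[stn]], c(0, 0, 0),
         geometry$sphere_radii[["trunk"]], paste0("joint_", stn))

  # legs
  lmk <- list()
  for (leg in leg_ids()) {
    side <- if (startsWith(leg, "L")) 1 else -1
    pr <- as.integer(substr(leg, 2, 2))
    att <- geometry$attachments[geometry$attachments$pair == pr, ]
    seg_x_ant <- switch(att$segment,
                        prothorax = st[["head_post"]],
                        mesothorax = st[["pro_post"]],
                        metathorax = st[["meso_post"]])
    A <- c(seg_x_ant - att$along, side * att$lateral, h)
    L <- geometry$legs[geometry$legs$pair == pr, ]
    al <- a[[paste0(leg, "_alpha")]]
    be <- a[[paste0(leg, "_beta")]]
    ga <- a[[paste0(leg, "_gamma")]]
    e <- c(sin(al), side * cos(al), 0)          # horizontal leg axis
    cxtr <- A + L$coxa * e
    d_f <- e * cos(be) + c(0, 0, sin(be))
    feti <- cxtr + L$femur * d_f
    psi <- be - (pi - ga)                       # tibia elevation in leg plane
    d_t <- e * cos(psi) + c(0, 0, sin(psi))
    tita <- feti + L$tibia * d_t

    lmk[[paste(leg, "CxTr")]] <- cxtr
    lmk[[paste(leg, "FeTi")]] <- feti
    lmk[[paste(leg, "TiTa")]] <- tita

    push(1, A, cxtr, geometry$leg_radii[["coxa"]], paste0(leg, "_coxa"))
    push(1, cxtr, feti, geometry$leg_radii[["femur"]], paste0(leg, "_femur"))
    push(1, feti, tita, geometry$leg_radii[["tibia"]], paste0(leg, "_tibia"))
    push(0, A, c(0, 0, 0), geometry$sphere_radii[["attach"]], paste0(leg, "_attach"))
    push(0, cxtr, c(0, 0, 0), geometry$sphere_radii[["CxTr"]], paste0(leg, "_CxTr"))
    push(0, feti, c(0, 0, 0), geometry$sphere_radii[["FeTi"]], paste0(leg, "_FeTi"))
    push(0, tita, c(0, 0, 0), geometry$sphere_radii[["TiTa"]], paste0(leg, "_TiTa"))
  }

  for (i in seq_along(geometry$trunk_landmarks)) {
    lbl <- names(geometry$trunk_landmarks)[i]
    lmk[[lbl]] <- station_pts[[geometry$trunk_landmarks[[i]]]]
  }

  nm <- landmark_names(geometry)
  lm_mat <- do.call(rbind, lmk[nm])
  dimnames(lm_mat) <- NULL
  landmarks <- tibble::tibble(landmark = nm, x = lm_mat[, 1],
                              y = lm_mat[, 2], z = lm_mat[, 3])
  pm <- do.call(rbind, prim)
  primitives <- tibble::tibble(type = ifelse(pm[, 1] == 1, "cylinder", "sphere"),
                               x1 = pm[, 2], y1 = pm[, 3], z1 = pm[, 4],
                               x2 = pm[, 5], y2 = pm[, 6], z2 = pm[, 7],
                               radius = pm[, 8], part = parts)
  structure(list(landmarks = landmarks, primitives = primitives,
                 scale = geometry$scale),
            class = "posture3d")
}

#' @export
print.posture3d <- function(x, ...) {
  cat("<posture3d> ", nrow(x$landmarks), " landmarks, ",
      nrow(x$primitives), " primitives (scale ", x$scale, ")\n", sep = "")
  invisible(x)
}

#' Append estimated distal render primitives
#'
#' Adds the body parts that are rendered but not tracked as landmarks: the
#' six tarsi, obtained by extending each tibia's direction beyond the
#' tibia-tarsus joint by the tarsus length and clamping the tip to the
#' ground plane (z >= 0), and the abdomen, collinear with the metathorax
#' axis behind its posterior boundary.
#'
#' @param posture a `posture3d` from [forward_kinematics()].
#' @param geometry the [body_geometry()] used to build it.
#' @return The posture with tarsus and abdomen primitives appended.
#' @export
estimate_distal_points <- function(posture, geometry = default_geometry()) {
  stopifnot(inherits(posture, "posture3d"))
  lm <- posture$landmarks
  get <- function(lbl) unlist(lm[lm$landmark == lbl, c("x", "y", "z")])
  st <- trunk_stations(geometry)
  prim <- posture$primitives

  rows <- list()
  add <- function(type, p1, p2, r, part) {
    p1 <- unname(p1); p2 <- unname(p2)
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      type = type, x1 = p1[1], y1 = p1[2], z1 = p1[3],
      x2 = p2[1], y2 = p2[2], z2 = p2[3], radius = r, part = part)
  }

  for (leg in leg_ids()) {
    feti <- get(paste(leg, "FeTi"))
    tita <- get(paste(leg, "TiTa"))
    d <- tita - feti
    len <- sqrt(sum(d^2))
    pr <- as.integer(substr(leg, 2, 2))
    tars <- geometry$legs$tarsus[geometry$legs$pair == pr]
    tip <- if (len > 0) tita + tars * d / len else tita
    tip[3] <- max(tip[3], 0)
    add("cylinder", tita, tip, geometry$leg_radii[["tarsus"]],
        paste0(leg, "_tarsus"))
    add("sphere", tip, c(0, 0, 0), geometry$sphere_radii[["tip"]],
        paste0(leg, "_tip"))
  }
  meta_post <- c(st[["meta_post"]], 0, geometry$height)
  abd_end <- meta_post - c(geometry$trunk[["abdomen"]], 0, 0)
  add("cylinder", meta_post, abd_end, geometry$trunk_radii[["abdomen"]],
      "trunk_abdomen")
  add("sphere", abd_end, c(0, 0, 0), geometry$sphere_radii[["trunk"]],
      "joint_abd_post")

  posture$primitives <- dplyr::bind_rows(prim, rows)
  posture
}

#' Full posture for one frame (kinematics + distal estimates)
#'
#' @inheritParams forward_kinematics
#' @return A `posture3d` with all render primitives.
#' @export
build_posture <- function(angles, geometry = default_geometry()) {
  estimate_distal_points(forward_kinematics(angles, geometry), geometry)
}
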