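test_that("default geometry is a valid 6-legged body of about 80 mm", {
  g <- default_geometry()
  expect_s3_class(g, "body_geometry")
  expect_equal(sum(g$trunk), 80)
  expect_equal(nrow(g$legs), 3)           # mirror-symmetric pairs -> 6 legs
  expect_length(landmark_names(g), 22)
  # left/right attachments mirror about the midline by construction
  p <- forward_kinematics(joint_angles(), g)
  for (pr in 1:3) {
    l <- unlist(p$landmarks[p$landmarks$landmark == paste0("L", pr, " CxTr"),
                            c("x", "y", "z")])
    r <- unlist(p$landmarks[p$landmarks$landmark == paste0("R", pr, " CxTr"),
                            c("x", "y", "z")])
    expect_equal(l[c("x", "z")], r[c("x", "z")])
    expect_equal(l[["y"]], -r[["y"]])
  }
})

test_that("landmark order is stable and matches the field's labels", {
  nm <- landmark_names()
  expect_length(nm, 22)
  expect_true("R2 FeTi" %in% nm)
  expect_identical(nm, landmark_names())
  expect_identical(nm[1:3], c("R1 CxTr", "R1 FeTi", "R1 TiTa"))
})

test_that("forward kinematics preserves segment lengths for any angles", {
  g <- default_geometry()
  set.seed(42)
  for (rep in 1:10) {
    a <- joint_angles()
    a[] <- a + runif(length(a), -1.2, 1.2)
    p <- forward_kinematics(a, g)
    lm <- p$landmarks
    pt <- function(l) unlist(lm[lm$landmark == l, c("x", "y", "z")])
    for (leg in c("R1", "R2", "R3", "L1", "L2", "L3")) {
      pr <- as.integer(substr(leg, 2, 2))
      fe <- g$legs$femur[g$legs$pair == pr]
      ti <- g$legs$tibia[g$legs$pair == pr]
      expect_equal(sqrt(sum((pt(paste(leg, "FeTi")) -
                               pt(paste(leg, "CxTr")))^2)), fe,
                   tolerance = 1e-9)
      expect_equal(sqrt(sum((pt(paste(leg, "TiTa")) -
                               pt(paste(leg, "FeTi")))^2)), ti,
                   tolerance = 1e-9)
    }
  }
})

test_that("a right-angled knee puts the foot joint at the trigonometric position", {
  g <- body_geometry(legs = tibble::tibble(pair = 1:3, coxa = c(4, 4, 4),
                                           femur = rep(10, 3),
                                           tibia = rep(10, 3),
                                           tarsus = rep(5, 3)))
  a <- joint_angles(R2_gamma = pi / 2)     # alpha = beta = 0
  p <- forward_kinematics(a, g)
  lm <- p$landmarks
  pt <- function(l) unlist(lm[lm$landmark == l, c("x", "y", "z")])
  expect_equal(sqrt(sum((pt("R2 FeTi") - pt("R2 CxTr"))^2)), 10,
               tolerance = 1e-12)
  expect_equal(sqrt(sum((pt("R2 TiTa") - pt("R2 CxTr"))^2)), 10 * sqrt(2),
               tolerance = 1e-12)
  # tibia points straight down at gamma = pi/2, beta = 0
  expect_equal(pt("R2 TiTa")[["z"]] - pt("R2 FeTi")[["z"]], -10,
               tolerance = 1e-12)
})

test_that("degenerate zero-length tibia collapses TiTa onto FeTi", {
  g <- body_geometry(legs = tibble::tibble(pair = 1:3, coxa = c(4, 4, 4),
                                           femur = rep(10, 3),
                                           tibia = rep(0, 3),
                                           tarsus = rep(5, 3)))
  p <- forward_kinematics(joint_angles(), g)
  lm <- p$landmarks
  expect_equal(unlist(lm[lm$landmark == "R1 TiTa", c("x", "y", "z")]),
               unlist(lm[lm$landmark == "R1 FeTi", c("x", "y", "z")]))
})

test_that("non-finite angles are rejected with a diagnostic", {
  a <- joint_angles()
  a[["R1_alpha"]] <- NaN
  expect_error(forward_kinematics(a), "R1_alpha")
})

test_that("geometry scaling is exact, invertible, and commutes with FK", {
  g <- default_geometry()
  expect_equal(scale_geometry(g, 1.0), g)
  expect_equal(scale_geometry(scale_geometry(g, 0.5), 2.0)$trunk, g$trunk)
  expect_equal(scale_geometry(g, 1.5)$legs$femur, g$legs$femur * 1.5)
  expect_error(scale_geometry(g, 0), "positive")
  expect_error(scale_geometry(g, -1), "positive")

  set.seed(7)
  a <- joint_angles()
  a[] <- a + runif(length(a), -1, 1)
  for (s in c(0.5, 0.7, 1.3, 1.5)) {
    p1 <- forward_kinematics(a, scale_geometry(g, s))
    p0 <- forward_kinematics(a, g)
    expect_equal(as.matrix(p1$landmarks[, c("x", "y", "z")]),
                 s * as.matrix(p0$landmarks[, c("x", "y", "z")]),
                 tolerance = 1e-12)
  }
})

test_that("mirror symmetry: swapping sides and negating y reproduces the posture", {
  g <- default_geometry()
  set.seed(11)
  a <- joint_angles()
  for (leg in c("R1", "R2", "R3", "L1", "L2", "L3"))
    for (dof in c("alpha", "beta", "gamma"))
      a[[paste0(leg, "_", dof)]] <- a[[paste0(leg, "_", dof)]] + runif(1, -1, 1)
  b <- a
  for (pr in 1:3) for (dof in c("alpha", "beta", "gamma")) {
    b[[paste0("L", pr, "_", dof)]] <- a[[paste0("R", pr, "_", dof)]]
    b[[paste0("R", pr, "_", dof)]] <- a[[paste0("L", pr, "_", dof)]]
  }
  pa <- forward_kinematics(a, g)$landmarks
  pb <- forward_kinematics(b, g)$landmarks
  swap <- function(l) chartr("LR", "RL", l)
  for (i in seq_len(nrow(pa))) {
    j <- which(pb$landmark == swap(pa$landmark[i]))
    expect_equal(c(pa$x[i], -pa$y[i], pa$z[i]),
                 c(pb$x[j], pb$y[j], pb$z[j]), tolerance = 1e-12)
  }
})

test_that("distal estimates clamp tarsi to the ground and align the abdomen", {
  g <- default_geometry()
  # steep depression drives the extended tarsus below ground -> clamped
  a <- joint_angles(R1_beta = -0.3, R1_gamma = pi / 2)
  p <- estimate_distal_points(forward_kinematics(a, g), g)
  tars <- p$primitives[p$primitives$part == "R1_tarsus", ]
  expect_equal(nrow(tars), 1)
  expect_gte(tars$z2, 0)
  # abdomen endpoint sits one abdomen length behind the metathorax posterior
  abd <- p$primitives[p$primitives$part == "trunk_abdomen", ]
  expect_equal(sqrt((abd$x1 - abd$x2)^2 + (abd$y1 - abd$y2)^2 +
                      (abd$z1 - abd$z2)^2),
               g$trunk[["abdomen"]], tolerance = 1e-12)
  expect_equal(abd$y2, 0)                  # collinear with the body axis
  # scaled geometry scales the abdomen primitive too
  gs <- scale_geometry(g, 1.3)
  ps <- build_posture(joint_angles(), gs)
  abds <- ps$primitives[ps$primitives$part == "trunk_abdomen", ]
  expect_equal(abs(abds$x1 - abds$x2), gs$trunk[["abdomen"]],
               tolerance = 1e-12)
})

test_that("trunk landmark choice is configurable", {
  g <- body_geometry(trunk_landmarks = c(HeadPost = "head_post",
                                         ProMeso = "pro_post",
                                         MesoMeta = "meso_post",
                                         MetaAbd = "meta_post"))
  expect_true("HeadPost" %in% landmark_names(g))
  p <- forward_kinematics(joint_angles(), g)
  expect_equal(nrow(p$landmarks), 22)
  expect_error(body_geometry(trunk_landmarks = c(A = "nowhere", B = "pro_post",
                                                 C = "meso_post",
                                                 D = "meta_post")),
               "unknown trunk station")
})
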