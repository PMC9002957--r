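# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_model <- function() fixture("model", default_model)

fx_rig <- function() fixture("rig", function() make_rig(8, 4))

fx_walk2 <- function() fixture("walk2", function()
  generate_motion(motion_spec("walking", cadence = 1, n_cycles = 2,
                              frame_rate = 30, seed = 7), fx_model()))

fx_walk2_obs_clean <- function() fixture("walk2_obs_clean", function()
  observe_rig(fx_walk2(), fx_rig(), corruption_spec()))

# random world point comfortably inside the capture volume
random_point <- function() c(stats::runif(1, -0.5, 0.5),
                             stats::runif(1, 0.4, 1.6),
                             stats::runif(1, -0.5, 0.5))

# exact projections of a 3D point through a rig
project_all <- function(x, rig) {
  t(vapply(rig, function(cm) as.numeric(project_point(x, cm)), numeric(2)))
}

# independent plain (unweighted, all-camera) DLT for oracle checks
oracle_dlt <- function(uv, rig, use = seq_len(nrow(uv))) {
  A <- NULL
  for (i in use) {
    P <- gaitkit:::projection_matrix(rig[[i]])
    A <- rbind(A,
               uv[i, 1] * P[3, ] - P[1, ],
               uv[i, 2] * P[3, ] - P[2, ])
  }
  v <- svd(A)$v[, 4]
  v[1:3] / v[4]
}

oracle_mean_residual <- function(x, uv, rig, use) {
  mean(vapply(use, function(i) {
    p <- project_point(x, rig[[i]])
    sqrt(sum((p - uv[i, ])^2))
  }, numeric(1)))
}
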