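# shared fixtures: small phantoms and trajectories, built in code at test
# time; sizes chosen so the whole suite stays desk-scale

small_phantom <- function(seed = 1, contrast = "fdg_like") {
  make_phantom(shape = c(36, 36, 36), spacing = c(5, 5, 5),
               contrast = contrast, seed = seed)
}

study_phantom <- function(seed = 1, contrast = "fdg_like") {
  make_phantom(seed = seed, contrast = contrast)
}

# trajectory with a single non-reference frame holding a fixed transform
two_frame_trajectory <- function(transform, center) {
  motion_trajectory(list(rigid_transform(center = center), transform),
                    uniform_timing(2, 30), reference_index = 1L)
}

# max probe-point discrepancy (mm) between two trajectories, worst frame
probe_recovery_error <- function(truth, est, center, offset_mm = 70) {
  ant <- center + c(0, offset_mm, 0)
  post <- center - c(0, offset_mm, 0)
  vapply(seq_along(truth$transforms), function(f) {
    ea <- apply_transform(truth$transforms[[f]], ant) -
      apply_transform(est$transforms[[f]], ant)
    ep <- apply_transform(truth$transforms[[f]], post) -
      apply_transform(est$transforms[[f]], post)
    max(sqrt(sum(ea^2)), sqrt(sum(ep^2)))
  }, 0)
}

random_rigid <- function(center = c(0, 0, 0), rot_max = 3, trans_max = 4) {
  rigid_transform(stats::runif(3, -rot_max, rot_max),
                  stats::runif(3, -trans_max, trans_max), center)
}
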