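# Shared fixtures, all generated in code at test time.

# High-contrast, artifact-free ellipse scenes: the "easy" segmentation regime.
easy_organoid_dataset <- function(n, seed, canvas = 32) {
  sampler <- function(i, s) {
    organoidval:::with_seed(s, {
      a <- runif(1, canvas * 0.19, canvas * 0.38)
      b <- runif(1, canvas * 0.19, canvas * 0.38)
      organoid_params(
        canvas_size = c(canvas, canvas),
        center = c(runif(1, a + 1, canvas - a - 1), runif(1, b + 1, canvas - b - 1)),
        semi_axes = c(a, b),
        halo_density = 0, artifact_count = 0,
        rim_width = 2, rim_texture_amplitude = 5,
        background_gradient = c(230, 200), seed = s
      )
    })
  }
  make_dataset(n, sampler, seed = seed)
}

# A deterministic textured fixture (no randomness) for blur sweeps.
textured_fixture <- function(n = 48) {
  outer(seq_len(n), seq_len(n), function(i, j) {
    127.5 + 90 * sin(i / 2) * cos(j / 3) + 30 * ((i + j) %% 2)
  })
}

# A labeled image-id table (no pixel data) for decision simulations.
labeled_image_set <- function(groups = organoid_groups(), per_group = 40) {
  tibble::tibble(
    id = unlist(lapply(groups, function(g) sprintf("%s_%03d", g, seq_len(per_group)))),
    group = rep(groups, each = per_group)
  )
}

# Decision records realizing exact per-group confusion counts.
records_from_counts <- function(group, tp = 0, fp = 0, tn = 0, fn = 0,
                                n_experts = 8, time_s = 1) {
  truth <- if (group == "original") "real" else "generated"
  answers <- c(rep("real", tp + fp), rep("generated", tn + fn))
  n <- length(answers)
  tibble::tibble(
    expert_id = rep(sprintf("expert_%02d", seq_len(n_experts)), length.out = n),
    image_id = sprintf("%s_img_%04d", group, seq_len(n)),
    group = group, true_label = truth, answer = answers, time_s = time_s
  )
}

# Brute-force per-pixel confusion counting (oracle for seg_scores).
brute_confusion <- function(gt, u) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(gt))) for (j in seq_len(ncol(gt))) {
    if (gt[i, j] == 1 && u[i, j] == 1) tp <- tp + 1
    else if (gt[i, j] == 0 && u[i, j] == 1) fp <- fp + 1
    else if (gt[i, j] == 0 && u[i, j] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}
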