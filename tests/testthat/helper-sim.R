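## Shared fixtures: all synthetic, built in code at test time.

## Stated-world configuration with every noise source disabled.
noiseless_config <- function(...) {
  sim_config(noise_sd = 0, baseline_sd = 0, thickness_cv = 0,
             corneal_between_subject_sd = 0, center_jitter_px = 0,
             trace_jitter_px = 0, ...)
}

## Square map whose pixels are f(x_deg, y_deg) about the exact center;
## f must return values in [0, 255].
field_map <- function(f, n = 201, deg_per_px = 0.078125, mode = "fixed") {
  center <- c((n + 1) / 2, (n + 1) / 2)
  x <- matrix((seq_len(n) - center[2]) * deg_per_px, n, n, byrow = TRUE)
  y <- matrix((center[1] - seq_len(n)) * deg_per_px, n, n)
  px <- f(x, y)
  storage.mode(px) <- "integer"
  list(map = retardation_map(px, deg_per_px, mode, quality_score = 10),
       center = center)
}

## 90-degree counterclockwise rotation of a square matrix about its center.
rot90_ccw <- function(m) t(m)[nrow(m):1, ]

## Straight-line boundary trace helper.
line_trace <- function(cols, depths, name, valid = rep(TRUE, length(cols))) {
  boundary_trace(cols, depths, valid, name)
}

## Four scans (2 meridians x 2 offsets) for one simulated subject.
subject_scans <- function(cfg, subject_seed) {
  list(simulate_oct_boundaries(cfg, "horizontal", 1, subject_seed),
       simulate_oct_boundaries(cfg, "horizontal", -1, subject_seed),
       simulate_oct_boundaries(cfg, "vertical", 1, subject_seed),
       simulate_oct_boundaries(cfg, "vertical", -1, subject_seed))
}
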