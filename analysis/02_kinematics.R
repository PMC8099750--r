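#!/usr/bin/env Rscript
# Step 2: per-sample kinematic state (V, A, r, tau) from the simulated
# tracks, plus a per-track summary of maneuver start and deceleration.

library(taulanding)

tracks <- read_tracks("results/tracks.csv")
cfg <- pipeline_config()
kts <- compute_state_variables(tracks, cfg)
utils::write.csv(
  kts[, c("track_id", "t", "y", "V", "A", "r", "tau", "valid", "decel")],
  "results/kinematics.csv", row.names = FALSE)

per_track <- aggregate(cbind(u_start = u_start) ~ track_id,
                       unique(kts[, c("track_id", "u_start")]), mean)
cat(sprintf("Computed state variables for %d tracks.\n",
            length(unique(kts$track_id))))
cat(sprintf("Flight speed at maneuver start: median %.2f m/s [IQR %.2f-%.2f].\n",
            median(per_track$u_start, na.rm = TRUE),
            quantile(per_track$u_start, 0.25, na.rm = TRUE),
            quantile(per_track$u_start, 0.75, na.rm = TRUE)))
cat(sprintf("%.0f%% of valid samples lie in deceleration phases.\n",
            100 * mean(kts$decel[kts$valid])))
cat("Wrote results/kinematics.csv\n")
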