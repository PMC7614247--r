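# Qualitative fate-map and transient analyses on the illustrative
# neural-tube-style fixture. The parametrization shipped with the package is
# NOT a published model fit; these analyses demonstrate the workflow
# (fate maps across signal levels, transient time courses, channel ranking
# and ablation) and should be read qualitatively.
#
# Run from an R session with memnet installed:
#   source(system.file("examples", "neural_tube_fate_map.R", package = "memnet"))

library(memnet)

## Fate map at an intermediate signal level -------------------------------
model <- fixture_model("neural_tube4", p = 0.65)
partition <- default_partition(model)

fp <- find_fixed_points(model, c(0, 4), system = "full", n_starts = 256L)
print(generics::tidy(fp))

att <- stable_points(fp)[, partition$sub_names, drop = FALSE]
grid <- list(`Nkx2.2` = seq(0, 2.5, length.out = 15),
             Olig2 = seq(0, 2.5, length.out = 15))
bm <- basin_map(model, partition, grid, variants = c("full", "qss", "zms"),
                attractors = att)
print(generics::glance(bm))   # ZMs should agree with full better than QSS
print(ggplot2::autoplot(bm))

## Transient time courses at a different signal level ---------------------
model_lo <- fixture_model("neural_tube4", p = 0.9)
partition_lo <- default_partition(model_lo)
times <- seq(0, 30, length.out = 301)
trajs <- list(
  full = integrate_full(model_lo, c(0, 0), times, partition = partition_lo),
  qss = integrate_qss(model_lo, partition_lo, c(0, 0), times),
  zms = integrate_zms(model_lo, partition_lo, c(0, 0), times)
)
for (v in names(trajs)) {
  cat(v, ": final Nkx2.2 =", round(tail(trajs[[v]]$`Nkx2.2`, 1), 3),
      " peak Olig2 =", round(max(trajs[[v]]$Olig2), 3), "\n")
}

## Channel ranking and ablation -------------------------------------------
ch <- decompose_channels(model_lo, partition_lo)
rk <- rank_channels(ch, trajs$zms)
print(tibble::as_tibble(rk)[, c("channel", "score")])

top <- rk$channel[seq_len(4)]
ablated <- ablate_channels(model_lo, partition_lo, top)(c(0, 0), times)
cat("sup-norm deviation of top-4 ablation from full ZMs:",
    signif(max(abs(as.matrix(ablated[, partition_lo$sub_names]) -
                   as.matrix(trajs$zms[, partition_lo$sub_names]))), 3), "\n")
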