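#!/usr/bin/env Rscript
# Grid search for the super-resolution regularisation parameters lambda
# (regularisation weight) and delta (edge definition, relative to mean
# in-mask intensity) on the packaged phantom: frames are simulated with
# known transforms and phases, the cine is reconstructed for every
# (lambda, delta) pair, and the NRMSE against the phantom is reported.
# The ReconConfig() defaults were chosen from the minimum of this grid.
#
#   Rscript scripts/param_grid.R [--seed 1] [--out scratch/param_grid.csv]

suppressMessages(library(fetalcine4d))
suppressMessages(library(optparse))

opts <- parse_args(OptionParser(option_list = list(
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", type = "character",
                default = "scratch/param_grid.csv"))))

spec <- PhantomSpec(spacing = 1, nPhases = 12L)
chi <- makePhantomCine(spec)
geoms <- makeStackGeometries(3L, 6L, 64)
sim <- simulateFrames(chi, geoms, traj = NULL, framesPerSlice = 24L,
                      noiseSd = 0.05, seed = opts$seed, spec = spec)
grid <- VoxelGrid(c(26, 26, 26), 2)
hm <- heartMaskVolume(grid, spec)
idt <- lapply(sim$frames, function(f) RigidTransform())

lambdas <- c(0, 0.005, 0.01, 0.02, 0.05, 0.1)
deltas <- c(0.05, 0.1, 0.15, 0.25, 0.4)
res <- expand.grid(lambda = lambdas, delta = deltas)
res$nrmse <- NA_real_
for (i in seq_len(nrow(res))) {
    cfg <- ReconConfig(spacing = 2, nPhases = 12L, lambda = res$lambda[i],
                       delta = res$delta[i], nSR = 20L,
                       seed = opts$seed)
    rec <- reconstruct(sim$frames, idt, sim$theta, grid, cfg,
                       tRR = sim$tRR, mode = "cine",
                       truth = chi, truthMask = hm)
    res$nrmse[i] <- tail(rec$diagnostics$nrmse, 1)
    message(sprintf("lambda %.3f delta %.2f -> NRMSE %.4f",
                    res$lambda[i], res$delta[i], res$nrmse[i]))
}
dir.create(dirname(opts$out), showWarnings = FALSE, recursive = TRUE)
write.csv(res, opts$out, row.names = FALSE)
best <- res[which.min(res$nrmse), ]
message(sprintf("best: lambda %.3f delta %.2f (NRMSE %.4f)",
                best$lambda, best$delta, best$nrmse))
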