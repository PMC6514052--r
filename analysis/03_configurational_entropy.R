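#!/usr/bin/env Rscript
# Stage 3: quasi-harmonic configurational entropy validation and the
# apo-vs-bound ordering experiment.
#
# Gaussian ensembles with a prescribed mass-weighted covariance spectrum are
# the exact generative model behind the quasi-harmonic estimator, so the
# closed-form mode sum of the prescribed spectrum is ground truth. The
# "apo-like" ensemble doubles every mode's standard deviation relative to
# the "bound-like" one, mirroring the expectation that ligand binding
# rigidifies the domain and lowers its configurational entropy.

library(lbdtraj)

dir.create("results", showWarnings = FALSE)

lambda <- rep(c(0.003, 0.008, 0.015, 0.03, 0.05), 3)  # amu nm^2, 5 atoms
ge <- make_gaussian_ensemble(lambda, masses = rep(12.011, 5),
                             n_frames = 20000, seed = 3)
qh <- quasiharmonic_entropy(ge$trajectory, superpose = FALSE)
sc <- quasiharmonic_entropy(ge$trajectory, superpose = FALSE,
                            method = "schlitter")
cat(sprintf("closed-form quasi-harmonic entropy: %.2f J/mol/K\n",
            ge$entropy_quasiharmonic))
cat(sprintf("estimate from 20000 sampled frames: %.2f J/mol/K (%.3f%% off)\n",
            qh$total,
            100 * abs(qh$total - ge$entropy_quasiharmonic) /
              ge$entropy_quasiharmonic))
cat(sprintf("Schlitter upper-bound variant:      %.2f J/mol/K\n", sc$total))

lambda_bound <- rep(c(0.004, 0.01, 0.02), 4)
rows <- lapply(1:20, function(k) {
  apo <- make_gaussian_ensemble(4 * lambda_bound, masses = rep(12, 4),
                                n_frames = 2500, seed = 100 + k)
  bnd <- make_gaussian_ensemble(lambda_bound, masses = rep(12, 4),
                                n_frames = 2500, seed = 200 + k)
  data.frame(
    replicate = k,
    s_apo = quasiharmonic_entropy(apo$trajectory, superpose = FALSE)$total,
    s_bound = quasiharmonic_entropy(bnd$trajectory,
                                    superpose = FALSE)$total)
})
tab <- do.call(rbind, rows)
tab$apo_larger <- tab$s_apo > tab$s_bound
cat(sprintf(
  "apo-like entropy exceeded bound-like in %d/20 replicates (mean %.1f vs %.1f J/mol/K)\n",
  sum(tab$apo_larger), mean(tab$s_apo), mean(tab$s_bound)))
write.csv(tab, "results/03_entropy_ordering.csv", row.names = FALSE)
jsonlite::write_json(
  list(closed_form = ge$entropy_quasiharmonic, quasiharmonic = qh$total,
       schlitter = sc$total,
       mode_frequencies_rad_per_s = qh$mode_frequencies),
  "results/03_entropy_spectrum.json", auto_unbox = TRUE, digits = NA)
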