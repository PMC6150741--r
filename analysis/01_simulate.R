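#!/usr/bin/env Rscript
# Simulate the test-retest cohort: 14 subjects, two studies on consecutive
# days, two independent readers.
#
# The phantom emulates T2-weighted axial tumor volumes (96x96 in-plane at
# 0.68 mm, 10 sections at 7.8 mm pitch = 6 mm thickness + 1.8 mm gap) with
# a correlated intensity texture. Day-to-day change is a multiplicative
# within-subject error with a 10% CV (global gain drift plus block-level
# local change); each reader delineates the tumor independently, modelled
# as 1-voxel per-slice boundary jitter for reader 2.
#
# Volumes are binary NIfTI scratch output; only the manifest location is
# echoed for the next stage.

library(texrep)

out_dir <- "scratch/cohort"
unlink(out_dir, recursive = TRUE)

manifest <- simulate_cohort(
  n_subjects = 14,
  out_dir = out_dir,
  noise_cv = 0.10,
  mask_jitter = 1L,   # day-2 re-delineation by the same reader
  seed = 20260923L
)
manifest <- simulate_second_reader(manifest, mask_jitter = 1L,
                                   seed = 20260924L)

m <- read_manifest(manifest)
cat("cohort written:", length(unique(m$subject_id)), "subjects,",
    nrow(m), "studies (", nrow(m[m$reader_id == 1, ]), "reader-1 +",
    nrow(m[m$reader_id == 2, ]), "reader-2 )\n")
cat("manifest:", manifest, "\n")
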