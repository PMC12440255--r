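#!/usr/bin/env Rscript
# Simulate the study cohort: 31 infants (25 with maternal STAI scores),
# 27-trial sessions with 80% expected / 20% unexpected events, 100-Hz gaze
# with 5% signal loss, and per-trial dwell-time ratios (DTR) computed from
# the synthetic gaze. Writes the subject table, the trial-level DTR table
# and one example session export (gaze CSV + schedule CSV + sidecars).

suppressMessages(library(nidot))
dir.create("results", showWarnings = FALSE)
seed <- 2026

cohort <- generate_cohort(31, seed = seed)
subjects <- cohort$subjects
write.csv(subjects, "results/cohort_subjects.csv", row.names = FALSE)

rows <- vector("list", nrow(subjects))
for (i in subjects$subject) {
  sch <- generate_trial_schedule(27, 0.8, seed = seed + 100 * i)
  truth <- cohort_subject_truth(cohort, i)
  truth$dtr_true <- trial_dtr_truth(truth, sch, seed = seed + 100 * i + 1)
  gaze <- generate_gaze(sch, truth, seed = seed + 100 * i + 2)
  dtr <- compute_dtr(gaze, sch)
  incl <- subject_inclusion(dtr, sch)
  rows[[i]] <- data.frame(subject = i, trial = dtr$trial, condition = dtr$type,
                          dtr = dtr$dtr, dtr_true = truth$dtr_true,
                          valid_time_s = dtr$valid_time_s,
                          include = incl$include)
  if (i == 1) {
    write_gaze_csv(gaze, "results/example_gaze_subject01.csv")
    write_schedule_csv(sch, "results/example_schedule_subject01.csv")
  }
}
trials <- do.call(rbind, rows)
write.csv(trials, "results/dtr_trials.csv", row.names = FALSE)

jsonlite::write_json(list(seed = seed, n_subjects = nrow(subjects),
                          n_anxiety = sum(subjects$mother_completed),
                          anxiety_cfg = cohort$anxiety_cfg,
                          coupling_b1 = cohort$coupling_b1),
                     "results/cohort_params.json", auto_unbox = TRUE, digits = NA)

cat(sprintf("cohort: %d subjects (%d with maternal STAI), %d clinical (>40)\n",
            nrow(subjects), sum(subjects$mother_completed), sum(subjects$clinical)))
cat(sprintf("trials: %d rows, %d included subjects, mean DTR %.3f (expected) vs %.3f (unexpected)\n",
            nrow(trials), length(unique(trials$subject[trials$include])),
            mean(trials$dtr[trials$condition == "expected"], na.rm = TRUE),
            mean(trials$dtr[trials$condition == "unexpected"], na.rm = TRUE)))
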