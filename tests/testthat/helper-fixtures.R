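# Shared fixtures, built in code.

# Hill-shaped survival arms on a 0.05-month grid (months; k = median PFS).
hill_arm <- function(k, n, n_patients = 235, tmax = 60, label = "arm") {
  tg <- seq(0, tmax, by = 0.05)
  survival_table(tg, hill_viability(hill_params(k, n), tg),
                 n_patients = n_patients, label = label)
}

# A trial whose combination arm is the exact tCDA prediction at `rho`.
exact_trial <- function(rho, kA = 10, nA = 2, kB = 14, nB = 1.6,
                        n_patients = 235) {
  armA <- hill_arm(kA, nA, n_patients, label = "A")
  armB <- hill_arm(kB, nB, n_patients, label = "B")
  armAB <- survival_table(armA$times,
                          tcda_survival(armA$survival, armB$survival, rho),
                          n_patients = n_patients, label = "AB")
  trial_set(armA, armB, armAB, combination_id = paste0("exact rho=", rho))
}

# A dose matrix whose observed cells are the exact dCDA prediction at `rho`.
exact_matrix <- function(rho, hill_A = hill_params(1, 2, "A"),
                         hill_B = hill_params(2, 1.5, "B"),
                         doses_A = hill_A$k * 2^seq(-2, 2, length.out = 6),
                         doses_B = hill_B$k * 2^seq(-2, 2, length.out = 6)) {
  pred <- outer(seq_along(doses_A), seq_along(doses_B),
                Vectorize(function(i, j)
                  dcda_viability(hill_A, hill_B, doses_A[i], doses_B[j], rho)))
  dose_matrix(doses_A, doses_B, pred,
              mono_A = hill_viability(hill_A, doses_A),
              mono_B = hill_viability(hill_B, doses_B),
              combination_id = paste0("exact rho=", rho))
}

write_tmp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
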