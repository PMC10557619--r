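# Shared fixtures: a quadratic lifespan truth peaking at 25 y and helpers
# to turn generated tables into fitting data frames.

# f(a) = 0.3 + 0.016 a - 0.00032 a^2: vertex at 25 y, f(25) = 0.5.
# Dynamic range on [0, 100] is f(25) - f(100) = 1.8, so 5% noise = 0.09.
quad_params <- c(0.3, 0.016, -0.00032)
quad_range <- 1.8

quad_truth <- function(noise_sd = 0.05 * quad_range, ya_offset = 0,
                       sex_effect = 0) {
  truth_record("b1", "FA", "quadratic", params = quad_params,
               ya_offset = ya_offset, noise_sd = noise_sd,
               sex_effect = sex_effect)
}

# one bundle x one feature table -> data.frame for fit_trajectory()
fit_data <- function(table, feature = "FA") {
  data.frame(age = table$age, value = table[[feature]], sex = table$sex,
             subject_id = table$subject_id, stringsAsFactors = FALSE)
}

quad_fit_data <- function(n_per_cohort, seed, noise_sd = 0.05 * quad_range) {
  gen <- generate_feature_table(list(quad_truth(noise_sd = noise_sd)),
                                default_cohorts(n_per_cohort), seed = seed)
  fit_data(gen$table)
}

# independent brute-force BH step-up: reject the m' smallest finite p where
# m' = max{i : p_(i) <= i q / m}
brute_force_bh <- function(p, q) {
  mask <- rep(FALSE, length(p))
  fin <- which(is.finite(p))
  m <- length(fin)
  if (m == 0) return(mask)
  ord <- fin[order(p[fin])]
  ok <- which(p[ord] <= seq_len(m) * q / m)
  if (length(ok)) mask[ord[seq_len(max(ok))]] <- TRUE
  mask
}

# plain-loop Pearson correlation from first principles
pearson_by_hand <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}
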