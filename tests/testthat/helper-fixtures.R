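# shared fixtures built in code

# reported blood clearance: 91% at 6.5 min, 9% at 4.4 h (264 min)
blood_truth_model <- function() {
  retention_model(
    data.frame(amplitude = c(0.91, 0.09), rate_per_min = log(2) / c(6.5, 264)),
    organ = "blood", constrained_to_unity_at_zero = TRUE)
}

# image-derived early points plus the venous schedule
blood_schedule_min <- c(2, 5, 10, 20, 30, 45, 85, 175, 245)

# one noisy blood refit; returns the recovered half-lives (min)
refit_blood_half_lives <- function(noise_cv = 0.02) {
  m <- blood_truth_model()
  u <- predict(m, blood_schedule_min)
  y <- pmax(u * (1 + rnorm(length(u), 0, noise_cv)), 0)
  fit <- fit_retention(
    data.frame(time_min = blood_schedule_min, value = y),
    n_components = 2, constrain_unity = TRUE)
  sort(fit$components$half_life_min)
}

# a nuclide with negligible physical decay, for no-decay limiting cases
no_decay_nuclide <- function() {
  new_nuclide("stable-ish", 1e12,
              tibble::tibble(kind = "photon", yield = 1, energy_MeV = 0.5))
}
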