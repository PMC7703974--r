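# Shared fixtures: small designs and quick MCMC settings for tests.

quick_ctrl <- function(seed = 1, chains = 2, adapt = 150, warmup = 150,
                       draws = 200, thin = 1)
  mcmc_control(chains = chains, adapt = adapt, warmup = warmup, draws = draws,
               thin = thin, seed = seed)

small_design <- function(n_participants = 4, repeated_reps = 2,
                         n_nonrepeated = 8)
  study_design(n_participants = n_participants, repeated_reps = repeated_reps,
               n_nonrepeated = n_nonrepeated)

# Closed-form off-tangent crossing time from lane centre: the chord from a
# point on a circle of radius R to the circle of radius R + d has length
# sqrt(2 R d + d^2); at constant speed v the crossing takes sqrt(2Rd+d^2)/v.
offtangent_closed_form <- function(radius, speed, half_width)
  sqrt(2 * radius * half_width + half_width^2) / speed
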