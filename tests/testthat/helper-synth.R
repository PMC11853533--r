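# Shared fixtures, generated in code and cached for the whole run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fn()
  .fixtures[[name]]
}

pattern_schedule <- function() fixture("pattern", function() build_default_schedule("pattern"))
frequency_schedule <- function() fixture("frequency", function() build_default_schedule("frequency"))

# reduced-width TCN used wherever a pupil classifier must actually be fit;
# same architecture family as the full model, sized for unit-test budgets
small_tcn_spec <- function() {
  tcn_spec(filters = c(16, 16, 8), dilations = c(1, 2, 4),
           batch_size = 16, dropout = 0.3)
}

# one subject's pupil tensors + labels at a given constriction gain
make_pupil_tensors <- function(n, seed, gain = 0.8, subject_scale = 1,
                               schedule = pattern_schedule()) {
  cfg <- synth_config(seed = seed, plr_constriction_gain = gain)
  labs <- rep_len(1:4, n)
  tens <- lapply(seq_len(n), function(i) {
    pt <- synth_pupil_trial(cfg, schedule, labs[i],
                            subject_scale = subject_scale,
                            seed = seed * 1000 + i)
    cwt_features(normalize_pupil(crop_pupil(pt, 0, 4.5)))
  })
  list(tensors = tens, labels = labs)
}

random_spd <- function(c_dim, seed) {
  set.seed(seed)
  a <- matrix(stats::rnorm(c_dim * c_dim), c_dim)
  assert_spd(crossprod(a) + diag(0.1, c_dim))
}

# independent oracle for the affine-invariant distance: generalized
# eigenvalues of solve(a) %*% b, a route that never forms a^(-1/2)
air_oracle <- function(a, b) {
  lam <- eigen(solve(unclass(a)) %*% unclass(b), only.values = TRUE)$values
  sqrt(sum(log(Re(lam))^2))
}
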