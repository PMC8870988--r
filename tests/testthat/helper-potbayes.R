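# shared fixtures: everything is generated in code at test time

quick_cfg <- function(seed = 1) mh_config(preset = "quick", seed = seed)
desk_cfg <- function(seed = 1) mh_config(preset = "desk", seed = seed)

# a seeded GPD exceedance sample wrapped as an exceedances object
gpd_tail <- function(xi, sigma, m, seed = 1, u = 0, p = 0.9) {
  potbayes:::new_exceedances(rgpd(m, xi, sigma, seed = seed),
                             u = u, p = p, n_source = m)
}

# closed-form conjugate posterior means used as oracles for the
# baseline-scale samplers
levy_conjugate_mean <- function(x, a0 = 0.01, b0 = 0.01) {
  (a0 + length(x) / 2) / (b0 + sum(1 / x) / 2)
}
normal_conjugate_mean_asq <- function(x, a0 = 0.01, b0 = 0.01) {
  # inverse-gamma posterior on a^2: IG(a0 + n/2, b0 + sum(x^2)/2)
  (b0 + sum(x^2) / 2) / (a0 + length(x) / 2 - 1)
}
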