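# Shared fixture builders: everything is generated in code at test time.

# sparse noise-free scene: one colony per droplet, confined to droplet
# centres and with a narrow size spread so colonies never touch
sparse_scene <- function(seed = 3, n_x = 7, n_y = 8, noise = FALSE) {
  m <- make_printing_map(n_x, n_y, "mixed")
  render_scene(m, cells_exact = 1, confine_radius = 20,
               growth = list(sdlog = 0.2),
               noise = if (noise) default_scene_noise() else no_noise(),
               seed = seed)
}

no_noise <- function() list(background = 0, gradient = 0, sd = 0)

default_scene_noise <- function() list(background = 0.05, gradient = 0.05,
                                       sd = 0.02)

# genotype mask straight from an integer matrix (0 NONE / 1 A / 2 B)
mk_mask <- function(labels, pixel_size = 1) {
  genotype_mask(matrix(as.integer(labels), nrow(labels), ncol(labels)),
                pixel_size)
}

# random three-valued mask for oracle-equivalence and invariance tests
random_mask <- function(nr, nc, p_none = 0.3, seed = 1, pixel_size = 1) {
  set.seed(seed)
  lab <- matrix(sample(0:2, nr * nc, replace = TRUE,
                       prob = c(p_none, (1 - p_none) / 2, (1 - p_none) / 2)),
                nr, nc)
  mk_mask(lab, pixel_size)
}

# two touching spheres: narrow dark gap that a plain threshold bridges
touching_pair_stack <- function() {
  synth_sphere_stack(rbind(c(20, 12, 12), c(20, 29, 12)), radii = 8,
                     dim = c(40, 40, 24), smooth_sigma = 1.2)
}

# synthetic flow-cytometry event table: two fluorescence modes separated by
# the 2^9.5 threshold, scatter as a broad core plus outliers
flow_fixture <- function(n = 20000, f1 = 0.5, seed = 1) {
  set.seed(seed)
  g1 <- stats::runif(n) < f1
  data.frame(
    fsc = stats::rlnorm(n, log(5e4), 0.4),
    ssc = stats::rlnorm(n, log(2e4), 0.4),
    fluor = ifelse(g1, 2^stats::rnorm(n, 12, 0.5), 2^stats::rnorm(n, 7, 0.5)))
}

ang_mod90 <- function(err) {
  err <- err %% 90
  pmin(err, 90 - err)
}
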