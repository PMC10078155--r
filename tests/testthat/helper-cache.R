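# Lazily computed shared fixtures: expensive simulations are run once per
# test session and reused by the unit, property and acceptance suites.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

get_direction_table <- function() {
  cached("direction_table", run_direction_table())
}

get_input_scan <- function() {
  cached("input_scan", {
    p <- kndy_params()
    scan_input(p, I_exc_grid = seq(0, 0.6, length.out = 21), I_inh = 0.3)
  })
}

get_default_traj <- function() {
  cached("default_traj",
         kndy_simulate(kndy_params(), t_span = c(0, 300), dt_out = 0.1))
}

# Independent root-finding oracle: minimise the squared norm of the
# derivative field from a given start; returns the located state and the
# residual norm of the derivatives there.
find_kndy_fixed_point <- function(params, input, start) {
  obj <- function(y) {
    d <- kndy_derivatives(kndy_state(max(y[1], 0), max(y[2], 0),
                                     max(y[3], 0)), params, input)
    sum(d^2)
  }
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-16))
  opt <- stats::optim(opt$par, obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
  list(state = kndy_state(max(opt$par[1], 0), max(opt$par[2], 0),
                          max(opt$par[3], 0)),
       residual = sqrt(obj(opt$par)))
}

find_mepd_fixed_point <- function(params, drug, light_on) {
  obj <- function(y) {
    s <- mepd_state(max(y[1], 0), max(y[2], 0), max(y[3], 0), max(y[4], 0))
    sum(mepd_derivatives(s, params, drug, light_on)^2)
  }
  # crude forward-Euler relaxation provides an independent approach to the
  # attractor; Nelder-Mead then polishes it to root-finding accuracy
  y <- c(0.5, 0.5, 0.5, 0.5)
  h <- 0.1 * params$tau_m
  for (i in 1:2000) {
    d <- mepd_derivatives(mepd_state(y[1], y[2], y[3], y[4]), params, drug,
                          light_on)
    y <- pmax(unname(y + h * d), 0)
  }
  opt <- stats::optim(y, obj, method = "Nelder-Mead",
                      control = list(maxit = 20000, reltol = 1e-16))
  list(state = mepd_state(max(opt$par[1], 0), max(opt$par[2], 0),
                          max(opt$par[3], 0), max(opt$par[4], 0)),
       residual = sqrt(opt$value))
}
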