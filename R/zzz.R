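.onLoad <- function(libname, pkgname) {
  register_optimizee("sphere", function(params = list()) {
    params$name <- "sphere"
    benchmark_optimizee(params)
  })
  register_optimizee("rastrigin", function(params = list()) {
    params$name <- "rastrigin"
    benchmark_optimizee(params)
  })
  register_optimizee("mountain_car", function(params = list()) {
    max_steps <- if (is.null(params$max_steps)) 110L else as.integer(params$max_steps)
    mc_optimizee(max_steps = max_steps)
  })
  register_optimizer("ga", function(params = list()) do.call(optimizer_ga, params))
  register_optimizer("es", function(params = list()) do.call(optimizer_es, params))
  register_optimizer("gd", function(params = list()) do.call(optimizer_gd, params))
  register_optimizer("sa", function(params = list()) do.call(optimizer_sa, params))
  register_optimizer("ce", function(params = list()) do.call(optimizer_ce, params))
  register_optimizer("grid", function(params = list()) do.call(optimizer_grid, params))
  register_optimizer("enkf", function(params = list()) do.call(optimizer_enkf, params))
  invisible()
}
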