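# shared tiny fixtures for the suite

sphere_optimizee <- function(dim = 2L, low = -5, high = 5) {
  list(spec = param_spec(x = list(shape = dim, low = low, high = high)),
       simulate = function(ind, seed) -sum(ind$values$x^2))
}

empty_synapses <- function() {
  data.frame(pre = integer(0), post = integer(0),
             weight = numeric(0), delay = integer(0))
}

one_neuron_net <- function(params = lif_params()) {
  network_spec(1L, empty_synapses(), params = params)
}
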