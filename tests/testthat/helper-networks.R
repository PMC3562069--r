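# Small fixture networks built in code.

# first-order chain A -> B -> C with given rates
chain_network <- function(kab = 0.5, kbc = 0.2, a0 = 1000) {
  reaction_network(
    list(species("A", a0), species("B", 0), species("C", 0)),
    list(reaction("ab", "A", "B", rate_param = "kab"),
         reaction("bc", "B", "C", rate_param = "kbc")),
    c(kab = kab, kbc = kbc))
}

# reversible binding A + B <-> AB
binding_network <- function(kon = 1e-3, koff = 0.1, a0 = 1000, b0 = 800) {
  reaction_network(
    list(species("A", a0), species("B", b0), species("AB", 0)),
    list(reaction("bind", c("A", "B"), "AB", rate_param = "kon"),
         reaction("unbind", "AB", c("A", "B"), rate_param = "koff")),
    c(kon = kon, koff = koff))
}

# hand-built trajectory object (for death-time arithmetic tests)
fake_trajectory <- function(time, ...) {
  cols <- list(...)
  m <- cbind(time = time, do.call(cbind, cols))
  structure(m, class = c("trajectory", "matrix"))
}

# small population spec for fast tests
tiny_spec <- function(n = 8, cv = 0.4, seed = 11, p_direct = 0.12, ...) {
  population_spec(n_cells = n, cv = cv, seed = seed,
                  p_direct_death = p_direct, ...)
}

# cached small-population runs shared across tests in a file
.pop_cache <- new.env(parent = emptyenv())
cached_population <- function(tag, n = 12, cv = 0.4, seed = 11,
                              network = NULL, times = seq(0, 24, 0.2)) {
  key <- paste(tag, n, cv, seed, is.null(network))
  if (!is.null(.pop_cache[[key]])) return(.pop_cache[[key]])
  v <- model_variant(tag, network = network)
  r <- run_population(v, tiny_spec(n = n, cv = cv, seed = seed), times = times)
  .pop_cache[[key]] <- r
  r
}
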