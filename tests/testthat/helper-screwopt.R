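# Shared fixtures. Heavy artifacts (fully trained surrogates, the weight
# sweep) are computed once per test run and memoized here so several test
# files can assert against the same pipeline products.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

table1_learning <- function() {
  tab <- cached("table1", load_table1())
  tab[tab$split == "learning", ]
}

table1_testing <- function() {
  tab <- cached("table1", load_table1())
  tab[tab$split == "testing", ]
}

# full default-schedule surrogates (100 restarts each), trained once
full_surrogates <- function() {
  cached("surrogates", fit_surrogates(load_table1(), seed = 1L))
}

full_context <- function() {
  cached("context", {
    s <- full_surrogates()
    fitness_context(s$bending, s$pullout)
  })
}

# full 0.01-step weight sweep products, computed once
full_optimization <- function() {
  cached("optimization", {
    optimize_designs(full_context(), ga_cfg = ga_config(seed = 1001L))
  })
}

# cheap GA settings for operator- and plumbing-level tests
quick_ga <- function(weight = 0.5, seed = 1L) {
  ga_config(weight = weight, max_generations = 120L,
            convergence_window = 30L, seed = seed)
}

# fitness context over the closed-form pseudo-FE surfaces (no ANN involved)
pseudo_context <- function(params = pseudo_fe_params()) {
  cached("pseudo_ctx", fitness_context(
    function(x) pseudo_bending(x, params),
    function(x) pseudo_pullout(x, params)))
}

random_designs <- function(n, seed = 1L, space = design_space()) {
  set.seed(seed)
  x <- sapply(c("bp", "id", "prr", "p", "pha", "tw"), function(v) {
    runif(n, space$lower[[v]], space$upper[[v]])
  })
  matrix(x, ncol = 6L, dimnames = list(NULL, c("bp", "id", "prr", "p", "pha", "tw")))
}

random_chromosomes <- function(n, seed = 1L) {
  set.seed(seed)
  matrix(as.numeric(runif(n * 42L) < 0.5), nrow = n)
}
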