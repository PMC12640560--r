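# Shared expensive fixtures, built lazily once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  got <- .fixture_env[[name]]
  if (is.null(got)) {
    got <- builder()
    .fixture_env[[name]] <- got
  }
  got
}

# small, fast study conditions for unit tests (NOT the cohort defaults)
tiny_spec <- function(...) {
  args <- utils::modifyList(list(n_subjects = 2, seed = 101, n_fibers = 12,
                                 extent = 24),
                            list(...))
  do.call(cohort_spec, args)
}

tiny_opts <- function() pipeline_options(tol = 5e-6, max_iter = 6000)

# one solved homogeneous monopolar lead field, reused across tests
fixture_homog_field <- function() {
  fixture("homog_field", function() {
    lead <- build_lead("MDT3389")
    pl <- lead_placement(c(0, 0, 0), c(0, 0, 1), 0)
    opts <- solver_options(spacing = 0.5, extent = 21, tol = 1e-7)
    g <- default_solver_grid(lead, pl, opts)
    cond <- conductivity_homogeneous(g, 0.2)
    basis <- solve_lead_basis(lead, pl, cond, opts)
    s <- stim_setting(1, NULL, amplitude = 1, lead = lead)
    list(lead = lead, placement = pl, opts = opts, grid = g,
         basis = basis, sol = field_from_basis(basis, s))
  })
}

# a generated 2-subject cohort (deterministic, noise at defaults)
fixture_tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    cache <- new.env(parent = emptyenv())
    co <- generate_cohort(tiny_spec(), tiny_opts(), cache)
    list(cohort = co, cache = cache)
  })
}
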