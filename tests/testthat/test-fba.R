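test_that("FBA objective matches exhaustive vertex enumeration on all small networks", {
  for (m in toy_lp_models()) {
    sol <- run_fba(m)
    expect_identical(sol$status, "optimal")
    expect_equal(sol$objective, oracle_fba_objective(m), tolerance = 1e-9,
                 label = m$id)
    S <- model_matrix(m)
    expect_lt(max(abs(S %*% sol$fluxes)), 1e-9)
  }
})

test_that("FVA ranges contain the FBA flux and match the vertex oracle", {
  for (m in toy_lp_models()) {
    sol <- run_fba(m)
    fva <- run_fva(m, objective_fraction = 1)
    expect_true(all(fva$min <= sol$fluxes[fva$reaction] + 1e-7))
    expect_true(all(fva$max >= sol$fluxes[fva$reaction] - 1e-7))
    for (r in fva$reaction) {
      ref <- oracle_fva_range(m, r, sol$objective)
      expect_equal(unlist(fva[fva$reaction == r, c("min", "max")]),
                   ref, tolerance = 1e-6, ignore_attr = TRUE,
                   label = paste(m$id, r))
    }
  }
})

test_that("relaxing the objective fraction widens FVA ranges", {
  m <- toy_lp_models()$diamond
  tight <- run_fva(m, objective_fraction = 1)
  loose <- run_fva(m, objective_fraction = 0)
  expect_true(all(loose$min <= tight$min + 1e-8))
  expect_true(all(loose$max >= tight$max - 1e-8))
})

test_that("ion exchanges unblock sodium/potassium-utilising reactions", {
  m <- toy_cell_model()
  ion_rxns <- m$annotations$ion_reactions
  pre <- run_fva(m, ion_rxns, objective_fraction = 1)
  expect_true(all(abs(pre$min) < 1e-8 & abs(pre$max) < 1e-8))
  m2 <- add_ion_exchanges(m)
  expect_true(all(c("EX_na", "EX_k") %in% names(m2$reactions)))
  post <- run_fva(m2, ion_rxns, objective_fraction = 1)
  unblocked <- post$max - post$min > 1e-6 | abs(post$max) > 1e-6
  expect_gt(sum(unblocked), 0)
  ## idempotent
  m3 <- add_ion_exchanges(m2)
  expect_identical(names(m3$reactions), names(m2$reactions))
  ## growth route without ions is untouched
  expect_equal(run_fba(m2)$objective, run_fba(m)$objective,
               tolerance = 1e-6)
})

test_that("gluconeogenesis blocking zeroes PEPCK/FBPase and is sound", {
  m <- toy_cell_model()
  ## amino-acid feed, no glucose: biomass carbohydrate must come via
  ## gluconeogenesis in the unmodified model
  m_noglc <- set_bounds(m, "EX_glc", lb = 0)
  s1 <- run_fba(m_noglc)
  expect_gt(s1$objective, 1e-6)
  expect_gt(s1$fluxes[["FBP"]] + s1$fluxes[["PEPCK"]], 1e-6)
  s1b <- run_fba(block_gluconeogenesis(m_noglc))
  expect_lt(abs(s1b$objective), 1e-8)
  ## with glucose uptake 1 the blocked model still grows
  m_glc1 <- set_bounds(m, "EX_glc", lb = -1)
  sb <- run_fba(block_gluconeogenesis(m_glc1))
  expect_identical(sb$status, "optimal")
  expect_equal(sb$fluxes[["PEPCK"]], 0)
  expect_equal(sb$fluxes[["FBP"]], 0)
  expect_gt(sb$objective, 1e-6)
  ## blocking restricts the feasible set: objective never increases
  expect_lte(sb$objective, run_fba(m_glc1)$objective + 1e-8)
})

test_that("amino-acid bound tightening converges to the configured caps", {
  m <- toy_cell_model()
  out <- tighten_amino_acid_bounds(m, cap = 1, cap_tight = 0.5)
  expect_true(out$converged)
  expect_gt(length(out$iterations), 0)
  b <- model_bounds(out$model)
  aa <- m$annotations$amino_acid_exchanges
  expect_true(all(b[aa, "lb"] >= -1 - 1e-9 & b[aa, "ub"] <= 1 + 1e-9))
  ## already tight: no clamping rounds
  again <- tighten_amino_acid_bounds(out$model, cap = 1, cap_tight = 0.5)
  expect_identical(length(again$iterations), 0L)
  ## a tagged subset can carry the stricter cap
  m2 <- m
  m2$annotations$amino_acid_exchanges_tight <- c("EX_gln", "EX_glu")
  out2 <- tighten_amino_acid_bounds(m2, cap = 1, cap_tight = 0.5)
  b2 <- model_bounds(out2$model)
  expect_true(all(b2[c("EX_gln", "EX_glu"), "ub"] <= 0.5 + 1e-9))
})

test_that("offline exchange-flux conversion has the documented units and signs", {
  ## constant VCC 1e6 cells/mL at 514 pg/cell is 0.514 g CDW/L; a drop
  ## of 0.514 mmol/L over one hour is then -1 mmol/(g CDW h)
  q <- exchange_flux_from_offline(10, 10 - 0.514, 1e6, 1e6, 0, 1)
  expect_equal(q, -1, tolerance = 1e-12)
  expect_equal(exchange_flux_from_offline(5, 5, 1e6, 2e6, 0, 3), 0)
  ## doubling the cell dry weight halves the magnitude
  q2 <- exchange_flux_from_offline(10, 9, 1e6, 1e6, 0, 1, cdw_pg = 1028)
  expect_equal(q2, exchange_flux_from_offline(10, 9, 1e6, 1e6, 0, 1) / 2)
  ## log-mean biomass equals the analytic time average under exponential growth
  mu <- 0.04; t2 <- 10
  x1 <- 0.514; x2 <- x1 * exp(mu * t2)
  expect_equal((x2 - x1) / log(x2 / x1), x1 * (exp(mu * t2) - 1) / (mu * t2),
               tolerance = 1e-12)
  expect_error(exchange_flux_from_offline(1, 2, 1e6, 1e6, 5, 5), "t2")
})

test_that("flux comparison and flux-map export behave as contracts state", {
  m <- toy_lp_models()$branch
  a <- run_fba(m)
  expect_identical(compare_solutions(a, a)$n_differing, 0L)
  m2 <- set_bounds(m, "S1", ub = 0.2)
  b <- run_fba(m2)
  cmp <- compare_solutions(a, b, tol = 1e-6)
  expect_gt(cmp$n_differing, 0)
  expect_true("S1" %in% cmp$table$reaction[cmp$table$abs_diff > 1e-6])
  path <- withr::local_tempfile(fileext = ".json")
  out <- export_flux_map(a, m, path)
  map <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(names(map), names(m$reactions))
  resolved <- run_fba(out$constrained)
  expect_equal(resolved$fluxes, a$fluxes, tolerance = 1e-9)
})
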