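# Provenance manifests and configuration surface.

test_that("manifests capture config, seeds and input digests", {
  f <- tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", f)
  m <- runManifest(config = list(totalMoves = 1000, temps = tempLadder()),
                   seeds = c(run = 7L), inputs = f,
                   timings = c(build = 1.2))
  expect_s4_class(m, "RunManifest")
  expect_equal(m@fields$seeds[["run"]], 7L)
  expect_equal(length(m@fields$inputs), 1)
  out <- tempfile(fileext = ".json")
  writeManifest(m, out)
  back <- jsonlite::read_json(out)
  expect_equal(back$seeds$run, 7)
  expect_equal(back$config$totalMoves, 1000)
})

test_that("sampler configuration validates and records its seed", {
  cfg <- samplerConfig(seed = 123, totalMoves = 1000, exchangeEvery = 100)
  expect_equal(cfg@seed, 123L)
  expect_error(samplerConfig(temps = c(400, 300)), "increasing")
  expect_error(samplerConfig(equilFrac = 1), "equilFrac")
  ## the ladder spans 300-400 K in 8 exponential steps by default
  expect_equal(length(cfg@temps), 8)
  expect_equal(cfg@temps[1], 300)
  expect_equal(cfg@temps[8], 400)
  rat <- cfg@temps[-1] / cfg@temps[-8]
  expect_lt(diff(range(rat)), 1e-12)   # exponential spacing
})

test_that("force-field overrides are validated", {
  ff <- forceFieldParams(k_ev = 10)
  expect_equal(ffParam(ff, "k_ev"), 10)
  expect_error(forceFieldParams(nope = 1), "unknown")
  expect_error(ffParam(ff, "nope"), "no such")
  ## the noncanonical dihedral constant tracks the canonical one
  ff2 <- forceFieldParams(k_dihedral = 8)
  expect_equal(ffParam(ff2, "k_dihedral_noncanonical"), 2)
  expect_error(forceFieldParams(attr_eps = 0.9), "capped")
})
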