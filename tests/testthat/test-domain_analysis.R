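# a deterministic two-chain "complex" built from two micelle fixtures
# placed side by side
two_chain_complex <- function(n_per = 30, seed = 5, gap = 26) {
  a <- generate_structure(synthetic_spec(n_per, "two_layer_micelle",
                                         seed = seed))
  b <- generate_structure(synthetic_spec(n_per, "two_layer_micelle",
                                         seed = seed + 1))
  b$x <- b$x + gap
  b$chain <- "B"
  out <- rbind(a, b)
  attr(out, "label") <- "toy complex"
  class(out) <- c("eff_structure", "data.frame")
  out
}

test_that("analyze composes the lower-level operations exactly", {
  es <- two_chain_complex()
  sels <- list(selection("Complex", "A,B", mode = "complex"),
               selection("Chain A", "A", mode = "chain"))
  an <- analyze(es, sels)
  expect_equal(an$scores$name, c("Complex", "Chain A"))
  # by-hand composition for Chain A
  sub <- resolve_selection(es, sels[[2]])
  tt <- t_profile(sub, fit_gaussian(sub))
  oo <- o_profile(sub)
  expect_equal(an$scores$rd[2], rd_score(oo, tt))
  expect_equal(an$scores$k_opt[2], optimize_k(oo, tt)$k_opt)
  expect_equal(as.numeric(an$profiles[["Chain A"]]$t), as.numeric(tt))
  # complex row differs: its Gaussian spans both chains
  expect_false(isTRUE(all.equal(an$scores$rd[1], an$scores$rd[2])))
})

test_that("a fragment equal to its parent reproduces the parent's scores", {
  es <- two_chain_complex()
  sels <- list(
    selection("Complex", "A,B", mode = "complex"),
    selection("whole-as-fragment", "A,B", mode = "fragment_in_complex",
              parent = "Complex"))
  an <- analyze(es, sels)
  expect_equal(an$scores$rd[2], an$scores$rd[1], tolerance = 1e-12)
  expect_equal(an$scores$k_opt[2], an$scores$k_opt[1], tolerance = 1e-9)
})

test_that("fragment-in-complex slices the parent profiles and renormalises", {
  es <- two_chain_complex()
  sels <- list(
    selection("Complex", "A,B", mode = "complex"),
    selection("frag A1-10", "A:1-10", mode = "fragment_in_complex",
              parent = "Complex"))
  an <- analyze(es, sels)
  # oracle: slice by hand from the parent's profiles
  sub <- resolve_selection(es, sels[[1]])
  tt <- as.numeric(t_profile(sub, fit_gaussian(sub)))
  oo <- as.numeric(o_profile(sub))
  idx <- which(sub$chain == "A" & sub$resno <= 10)
  t_sl <- tt[idx] / sum(tt[idx]); o_sl <- oo[idx] / sum(oo[idx])
  expect_equal(as.numeric(an$profiles[["frag A1-10"]]$t), t_sl)
  expect_equal(an$scores$rd[2], rd_score(o_sl, t_sl))
  expect_equal(an$scores$n[2], 10)
  # a fragment-fitted analysis of the same residues differs (fresh Gaussian)
  an2 <- analyze(es, list(selection("D-frag", "A:1-10",
                                    mode = "individual_domain")))
  expect_false(isTRUE(all.equal(an2$scores$rd[1], an$scores$rd[2])))
})

test_that("fragment selections must reference a plan parent that contains them", {
  es <- two_chain_complex()
  expect_error(
    analyze(es, list(selection("orphan", "A:1-5",
                               mode = "fragment_in_complex",
                               parent = "nope"))),
    class = "fodm_selection_error")
  expect_error(
    analyze(es, list(selection("Chain A", "A", mode = "chain"),
                     selection("outside", "B:1-5",
                               mode = "fragment_in_complex",
                               parent = "Chain A"))),
    class = "fodm_selection_error")
})

test_that("inverted fixture scores higher K than the micelle at chain level", {
  mic <- generate_structure(synthetic_spec(60, "two_layer_micelle", seed = 2))
  inv <- generate_structure(synthetic_spec(60, "inverted_micelle", seed = 2))
  k_m <- analyze(mic, selection("m", "A", mode = "chain"))$scores$k_opt
  k_i <- analyze(inv, selection("i", "A", mode = "chain"))$scores$k_opt
  expect_gt(k_i, k_m)
})

test_that("core residues follow the AND criterion and are monotone in the threshold", {
  expect_equal(core_residues(c(0.02, 0.005, 0.02),
                             c(0.02, 0.02, 0.005))$indices, 1L)
  expect_equal(core_residues(rep(0.02, 50), rep(0.02, 50))$indices, 1:50)
  expect_length(core_residues(rep(0.02, 50), rep(0.02, 50), 1.0)$indices, 0)
  tt <- as.numeric(t_profile(micelle_es(seed = 8)))
  oo <- as.numeric(o_profile(micelle_es(seed = 8)))
  prev <- core_residues(tt, oo, 0)$indices
  for (thr in c(0.005, 0.01, 0.02, 0.05)) {
    cur <- core_residues(tt, oo, thr)$indices
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("plans read back as resolvable selection grids", {
  es <- two_chain_complex()
  plan_path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "structure: toy.pdb",
    "selections:",
    "  - {name: Complex, mode: complex, units: \"A,B\"}",
    "  - {name: DD1, mode: domain_set, units: \"A:1-10,B:1-10\"}",
    "  - {name: frag1, mode: fragment_in_complex, units: \"A:1-10\",",
    "     parent: Complex}"), plan_path)
  plan <- read_plan(plan_path)
  expect_length(plan$selections, 3)
  expect_equal(plan$selections[[2]]$mode, "domain_set")
  an <- analyze(es, plan$selections)
  expect_equal(nrow(an$scores), 3)
  expect_equal(an$scores$n, c(60, 20, 10))
})

test_that("packaged plans for the published analyses parse cleanly", {
  plans <- list.files(system.file("extdata", "plans", package = "fodm"),
                      full.names = TRUE)
  expect_length(plans, 5)
  for (p in plans) {
    plan <- read_plan(p)
    expect_gt(length(plan$selections), 0)
    for (s in plan$selections)
      if (s$mode == "fragment_in_complex")
        expect_true(s$parent %in% vapply(plan$selections, `[[`,
                                         character(1), "name"))
  }
})

test_that("score export embeds the convention record and round-trips", {
  es <- two_chain_complex()
  an <- analyze(es, selection("Complex", "A,B", mode = "complex"))
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_scores(an, csv = csv, json = json)
  first <- readLines(csv, n = 1)
  expect_match(first, "^# fodm conventions: .*scale=kd_norm")
  expect_match(first, "kernel_cutoff=9")
  back <- read.csv(csv, comment.char = "#")
  expect_equal(back$rd, an$scores$rd, tolerance = 1e-5)
  js <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(js$scores$k_opt, an$scores$k_opt)
  expect_equal(js$conventions$kernel_cutoff, 9)
})
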