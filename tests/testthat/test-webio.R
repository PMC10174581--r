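test_that("constructor enforces food-web invariants", {
  expect_error(foodweb(matrix(0, 2, 3)), "square")
  expect_error(
    foodweb(matrix(c(0, -1, 0, 0), 2, 2)), "negative"
  )
  expect_error(
    foodweb(matrix(0, 2, 2), species = c("A", "A")), "duplicate"
  )
  expect_error(
    foodweb(matrix(c(0, NA, 0, 0), 2, 2)), "missing or non-finite"
  )
  expect_error(
    foodweb(matrix(0, 2, 2), imports = c(1, 2, 3)), "imports"
  )
  # cannibalistic self-links are legal and counted as links
  w <- foodweb(diag(2), imports = c(1, 1))
  expect_equal(web_summary(w)$links, 2L)
})

test_that("canonical JSON round-trips and rejects broken schemas", {
  w <- fixture_web("chain3")
  path <- withr::local_tempfile(fileext = ".json")
  write_foodweb_json(w, path)
  w2 <- read_foodweb_json(path)
  expect_foodweb_equal(w, w2)
  expect_identical(w2$name, "chain3")
  expect_equal(sum(w2$flows > 0), 2L)

  broken <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  broken$flows <- NULL
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(broken, path2, auto_unbox = TRUE)
  expect_error(read_foodweb_json(path2), "flows")

  ragged <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ragged$flows[[1]] <- ragged$flows[[1]][-1]
  path3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(ragged, path3, auto_unbox = TRUE)
  expect_error(read_foodweb_json(path3), "ragged|flows")
})

test_that("flow-matrix TSV matches the JSON reader and reports cell errors", {
  w <- fixture_web("chain3")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_flow_matrix_tsv(w, tsv)
  w2 <- read_flow_matrix_tsv(tsv)
  expect_foodweb_equal(w, w2)

  # all-zero flows with imports only
  iso <- foodweb(matrix(0, 3, 3), imports = c(10, 10, 10))
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_flow_matrix_tsv(iso, tsv2)
  expect_equal(web_summary(read_flow_matrix_tsv(tsv2))$links, 0L)

  # a literal NA cell must be rejected with its coordinates
  lines <- readLines(tsv)
  lines[2] <- sub("\t5\t", "\tNA\t", lines[2])
  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, tsv3)
  expect_error(read_flow_matrix_tsv(tsv3), "row 1, column 2")

  # row labels out of order
  lines <- readLines(tsv)
  lines[2] <- sub("^A", "Z", lines[2])
  tsv4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, tsv4)
  expect_error(read_flow_matrix_tsv(tsv4), "labelled 'Z'")
})

test_that("supplementary-style JSON is read through a key mapping", {
  w <- fixture_web("two_prey")
  alien <- list(web_name = w$name, taxa = w$species, flow_matrix = w$flows,
                input = w$imports, output = w$exports, resp = w$respiration)
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(alien, path, auto_unbox = TRUE, digits = NA)

  mapping <- list(name = "web_name", species = "taxa", flows = "flow_matrix",
                  imports = "input", exports = "output",
                  respiration = "resp")
  expect_foodweb_equal(read_s1_foodweb(path, mapping), w)

  # same mapping via a YAML file
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(mapping, yml)
  expect_foodweb_equal(read_s1_foodweb(path, yml), w)

  # unknown structure fails loudly, listing the keys present
  expect_error(read_s1_foodweb(path), "taxa")
  # canonical files pass through with no mapping
  canon <- withr::local_tempfile(fileext = ".json")
  write_foodweb_json(w, canon)
  expect_foodweb_equal(read_s1_foodweb(canon), w)
})

test_that("environment augmentation caches baseline inflow and is idempotent", {
  w <- fixture_web("chain3")
  aug <- augment_web(w)
  expect_equal(aug$baseline_inflow, c(10, 5, 2))
  expect_equal(aug$env_out, c(10, 0, 0))
  expect_equal(aug$env_in, c(5, 3, 2))     # exports + respiration
  expect_equal(aug$web$flows, w$flows)     # inter-species flows untouched
  expect_identical(augment_web(aug), aug)  # idempotent

  # no imports anywhere: baseline is the plain column sum
  w0 <- foodweb(matrix(c(0, 2, 0, 0), 2, 2, byrow = TRUE),
                imports = c(3, 0))
  expect_equal(augment_web(w0)$baseline_inflow, c(3, 2))

  # zero-baseline species are flagged, not rejected
  expect_warning(augment_web(foodweb(matrix(0, 2, 2))), "zero baseline")
})

test_that("connectance follows C = C_n / S^2 for published S and link counts", {
  cases <- list(c(21, 61, 0.138), c(25, 104, 0.166), c(30, 77, 0.086),
                c(31, 332, 0.345), c(125, 1969, 0.126))
  for (cs in cases) {
    w <- make_web_with_links(cs[1], cs[2], seed = cs[1])
    s <- web_summary(w)
    expect_equal(s$s, cs[1])
    expect_equal(s$links, cs[2])
    expect_equal(round(s$connectance, 3), cs[3])
  }
  expect_equal(web_summary(foodweb(matrix(0, 3, 3), imports = 1))$connectance, 0)
})

test_that("weighted connectance reduces to C for uniform weights", {
  # any topology, all realized links at identical weight -> C_w = C
  set.seed(4)
  for (s in c(5, 9)) {
    l <- sample.int(s^2 - 1, 1)
    flows <- matrix(0, s, s)
    flows[sample.int(s^2, l)] <- 2.5
    w <- foodweb(flows, imports = rep(1, s))
    expect_equal(weighted_connectance(w), l / s^2, tolerance = 1e-12)
  }
  # a single link is one effective link
  one <- matrix(0, 4, 4); one[1, 2] <- 7
  expect_equal(weighted_connectance(foodweb(one, imports = rep(1, 4))),
               1 / 16)
  # no flow at all -> 0
  expect_equal(weighted_connectance(foodweb(matrix(0, 3, 3), imports = 1)), 0)
  # skewed weights cannot exceed the binary connectance
  w <- generate_niche_web(20, 0.2, seed = 11)
  s <- web_summary(w)
  expect_lte(s$weighted_connectance, s$connectance)
  expect_gt(s$weighted_connectance, 0)
})
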