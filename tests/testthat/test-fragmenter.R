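# BRICS, Murcko and functional-group fragmentation.

test_that("BRICS rule table has the full 16-environment structure", {
  rules <- brics_rules()
  expect_equal(nrow(rules), 16L)
  expect_equal(rules$label, 1:16)
  # every environment SMARTS compiles in the package's matcher
  for (s in rules$smarts) expect_s3_class(parse_smarts(s), "sme_smarts")
  pairs <- attr(rules, "compatible")
  expect_true(all(vapply(pairs, length, 1L) == 2L))
  expect_true(all(unlist(pairs) %in% 1:16))
})

test_that("BRICS fragments match reference decompositions", {
  # ethane has no BRICS-cleavable bond
  fr <- brics_fragments("CC")
  expect_length(fr, 1L)
  expect_equal(fr[[1]]$atom_indices, c(0L, 1L))

  # anisole cleaves at the aryl ether bond (L3-L16): {C,O} + ring
  fr <- brics_fragments("COc1ccccc1")
  sets <- lapply(fr, `[[`, "atom_indices")
  expect_setequal(lapply(sets, paste, collapse = ","),
                  list("0,1", "2,3,4,5,6,7"))

  # ethyl benzoate: ester splits into ethyl/O/acyl/ring pieces
  fr <- brics_fragments("CCOC(=O)c1ccccc1")
  sets <- vapply(fr, function(s) paste(s$atom_indices, collapse = ","), "")
  expect_setequal(sets, c("0,1", "2", "3,4", "5,6,7,8,9,10"))
})

test_that("BRICS atom sets partition the heavy atoms of random molecules", {
  lib <- fixture_library()
  for (s in lib$smiles) {
    mol <- parse_smiles(s)
    fr <- brics_fragments(mol)
    idx <- sort(unname(unlist(lapply(fr, `[[`, "atom_indices"))))
    expect_identical(idx, seq_len(mol$n) - 1L)
  }
})

test_that("Murcko splitting gives scaffold plus side chains", {
  mu <- murcko_fragments("CC(=O)Oc1ccccc1C(=O)O")   # aspirin
  expect_length(mu, 3L)
  expect_equal(mu[[1]]$name, "c1ccccc1")
  idx <- sort(unlist(lapply(mu, `[[`, "atom_indices")))
  expect_identical(idx, 0:12)

  mu <- murcko_fragments("c1ccccc1")
  expect_length(mu, 1L)
  expect_length(mu[[1]]$atom_indices, 6L)

  expect_warning(out <- murcko_fragments("CCCCCC"), "no Murcko scaffold")
  expect_length(out, 0L)
})

test_that("Murcko partition holds on random ring-bearing molecules", {
  lib <- fixture_library()
  n_checked <- 0L
  for (s in lib$smiles) {
    mol <- parse_smiles(s)
    if (!any(mol$in_ring)) next
    mu <- suppressWarnings(murcko_fragments(mol))
    idx <- sort(unname(unlist(lapply(mu, `[[`, "atom_indices"))))
    expect_identical(idx, seq_len(mol$n) - 1L)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 400L)
})

test_that("fragmentation is deterministic", {
  s <- fixture_library()$smiles[17]
  f1 <- brics_fragments(s); f2 <- brics_fragments(s)
  expect_identical(f1, f2)
  m1 <- suppressWarnings(murcko_fragments(s))
  m2 <- suppressWarnings(murcko_fragments(s))
  expect_identical(m1, m2)
})

test_that("default functional-group catalog has 33 validated entries", {
  catal <- load_fg_catalog()
  expect_equal(nrow(catal), 33L)
  expect_false(anyDuplicated(catal$name) > 0L)
})

test_that("catalog loading validates custom files", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("# two valid entries", "hydroxyl\t[O;H1;D1]",
               "nitrile\tC#N"), tmp)
  cc <- load_fg_catalog(tmp)
  expect_equal(nrow(cc), 2L)

  writeLines(c("a\t[O;H1]", "a\t[N;H2]"), tmp)
  expect_error(load_fg_catalog(tmp), "duplicate")

  writeLines(c("bad\t[Q>>]"), tmp)
  expect_error(load_fg_catalog(tmp), "bad")
  expect_error(load_fg_catalog("/nonexistent/file.tsv"), "not found")
})

test_that("functional-group matches report one substructure per occurrence", {
  catal <- load_fg_catalog()
  fg <- functional_group_matches("CCO", catal)
  expect_setequal(vapply(fg, `[[`, "", "name"), c("hydroxyl", "methyl"))

  expect_length(functional_group_matches("C", catal), 0L)

  fg <- functional_group_matches("O=[N+]([O-])c1ccccc1", catal)
  nitro <- Filter(function(s) s$name == "nitro", fg)
  expect_length(nitro, 1L)
  expect_equal(nitro[[1]]$atom_indices, c(0L, 1L, 2L))

  # two nitro groups -> two separate substructures
  fg <- functional_group_matches("O=[N+]([O-])c1ccc(cc1)[N+](=O)[O-]", catal)
  expect_length(Filter(function(s) s$name == "nitro", fg), 2L)
})

test_that("substructure constructor enforces its invariants", {
  expect_error(substructure("BRICS", integer(0), "x"), "nonempty")
  expect_error(substructure("BRICS", c(-1L, 2L), "x"), ">= 0")
  s <- substructure("COMBINATION", c(3L, 1L, 1L), "c")
  expect_equal(s$atom_indices, c(1L, 3L))
})
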