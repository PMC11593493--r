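test_that("the minimal-cell fixture serializes with the expected SBML structure", {
  mc <- minimal_cell_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(mc$model, path)
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          c = "https://cfba-r.invalid/ns/cfba/v1")
  expect_identical(xml2::xml_attr(doc, "level"), "3")
  expect_identical(xml2::xml_attr(doc, "version"), "1")
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  expect_length(sp, 4L)
  roles <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//s:species/s:annotation/c:species", ns), "role")
  expect_identical(sum(roles == "balanced"), 1L)
  expect_identical(sum(roles == "imbalanced"), 3L)
  # reversible flag is the SBML core attribute; no quota block is emitted
  expect_length(xml2::xml_find_all(doc, ".//c:listOfQuotas", ns), 0L)
  # the uptake feed segment is stored with explicit units
  seg <- xml2::xml_find_all(doc, ".//c:environment/c:segment", ns)
  expect_length(seg, 1L)
  expect_identical(xml2::xml_attr(seg, "end"), "2")
})

test_that("environment segments serialize one annotation entry each", {
  m <- cfba_model(
    species("x", weight = 1, contributes_to_weight = TRUE),
    list(reaction("r", c(x = 1), ub = 1)),
    environment = environment_profile("r", c(0, 2.5), c(2.5, 4),
                                      c(0, 0), c(1/3, 0.1)))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  ns <- c(c = "https://cfba-r.invalid/ns/cfba/v1")
  seg <- xml2::xml_find_all(xml2::read_xml(path), ".//c:segment", ns)
  expect_length(seg, 2L)
  # full-precision serialization: 1/3 survives the round trip bit-exactly
  m2 <- read_sbml(path)
  expect_identical(m2$environment$ub[1], 1/3)
})

test_that("write/read round-trip is the identity on randomized models", {
  for (s in 0:19) {
    m <- property_model(s)
    path <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, path)
    m2 <- read_sbml(path)
    expect_same_model(m, m2)
  }
})

test_that("round-trip preserves solver-relevant numerics bit-exactly", {
  m <- property_model(13)
  m$initial_weight <- 0.123456789123456789
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_identical(m2$initial_weight, m$initial_weight)
  expect_identical(m2$species$weight, m$species$weight)
  expect_identical(stoich_matrix(m2), stoich_matrix(m))
  o1 <- m$capacity[order(m$capacity$reaction_id), "kcat"]
  o2 <- m2$capacity[order(m2$capacity$reaction_id), "kcat"]
  expect_identical(o1, o2)
})

test_that("infinite bounds use SBML INF tokens and survive the round trip", {
  m <- cfba_model(
    species("x", weight = 1, contributes_to_weight = TRUE),
    list(reaction("r", c(x = 1), lb = 0, ub = Inf),
         reaction("rev", c(x = -1), reversible = TRUE, lb = -Inf, ub = Inf)))
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_identical(m2$reactions$r$ub, Inf)
  expect_identical(m2$reactions$rev$lb, -Inf)
})

test_that("files without cFBA role annotations fail with all offenders named", {
  plain <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="m"><listOfCompartments><compartment id="cell" constant="true"/>',
    '</listOfCompartments><listOfSpecies>',
    '<species id="s1" compartment="cell" hasOnlySubstanceUnits="true"',
    ' boundaryCondition="false" constant="false"/>',
    '<species id="s2" compartment="cell" hasOnlySubstanceUnits="true"',
    ' boundaryCondition="false" constant="false"/>',
    '</listOfSpecies></model></sbml>')
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(plain, path)
  expect_error(read_sbml(path), "s1.*s2|without cFBA role")
})

test_that("quota annotations referencing unknown species are rejected by id", {
  mc <- minimal_cell_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(mc$model, path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  # inject a quota block pointing at a ghost species
  txt <- sub("(<cfba:model[^>]*)/>",
             paste0("\\1>",
                    '<cfba:listOfQuotas><cfba:quota species="ghost" kind="min"',
                    ' value="0.1" timePoints="ALL"/></cfba:listOfQuotas>',
                    "</cfba:model>"),
             txt)
  writeLines(txt, path)
  expect_error(read_sbml(path), "ghost")
})

test_that("foreign annotation namespaces are ignored with a warning", {
  mc <- minimal_cell_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(mc$model, path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- sub("<annotation>",
             paste0("<annotation>",
                    '<foo:meta xmlns:foo="https://example.org/other">x</foo:meta>'),
             txt)
  writeLines(txt, path)
  expect_warning(m2 <- read_sbml(path), "foreign")
  expect_identical(nrow(validate_model(m2)), 0L)
})

test_that("unreadable or structurally broken files raise parse errors", {
  expect_error(read_sbml(file.path(tempdir(), "does-not-exist.xml")),
               "no such file")
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines("<notsbml/>", path)
  expect_error(read_sbml(path), "not an SBML")
})
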