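test_that("regulation facts match the literature statements", {
  d2 <- get_regulation_facts("DUSP2")
  expect_setequal(d2$inducers, c("ERK", "JNK"))
  expect_setequal(d2$substrates, c("ERK", "p38"))
  d5 <- get_regulation_facts("DUSP5")
  expect_equal(d5$inducers, "ERK")
  expect_equal(d5$substrates, "ERK")
  d9 <- get_regulation_facts("DUSP9")
  expect_equal(d9$inducers, "UNKNOWN")
  expect_equal(d9$substrates, "ERK")
  # numeric ids are accepted
  expect_equal(get_regulation_facts(16)$substrates, c("JNK", "p38"))
  expect_error(get_regulation_facts("DUSP6"), "not in the modelled")
  # inducers are UNKNOWN exactly for the four inference targets
  tab <- regulation_facts_table()
  expect_setequal(tab$dusp[is.na(tab$inducers)],
                  c("DUSP3", "DUSP9", "DUSP16", "DUSP23"))
  expect_true(all(nzchar(tab$substrates)))
})

test_that("hypothesis guards: known models reject one, unknown require one", {
  expect_error(build_model("DUSP2", "ERK"), "known")
  expect_error(build_model("DUSP9"), "hypothesis")
  expect_error(build_model("DUSP9", character(0)), "non-empty")
  expect_error(build_model("DUSP9", "AKT"), "unknown kinase")
})

test_that("built models contain the required scaffold", {
  m <- build_model("DUSP2")
  expect_true(all(c("Herceptin", "HER2", "ERK", "JNK", "p38",
                    "DUSP2", "Survival") %in% m$network$nodes))
  expect_equal(m$network$rule_text[["HER2"]], "not Herceptin")
  # induction combines by OR
  expect_match(m$network$rule_text[["DUSP2"]], "^ERK or JNK$")
  # substrate kinases carry the DUSP inhibition, non-substrates do not
  expect_match(m$network$rule_text[["ERK"]], "not DUSP2")
  expect_match(m$network$rule_text[["p38"]], "not DUSP2")
  expect_false(grepl("DUSP2", m$network$rule_text[["JNK"]]))
})

test_that("every shipped model reproduces its expected qualitative outcomes", {
  for (id in regulation_facts_table()$dusp) {
    res <- check_expected_outcomes(id)
    expect_true(all(res$ok),
                info = paste(id, ":", paste(res$node, res$observed,
                                            collapse = "; ")))
  }
})

test_that("DUSP5 oscillates and DUSP16 survival switches off, per the reported dynamics", {
  a5 <- model_attractor(build_model("DUSP5"))
  expect_equal(classify_node_pattern(a5, "DUSP5"), "OSCILLATING")
  expect_equal(classify_node_pattern(a5, "Survival"), "CONSTANT_ON")
  a16 <- model_attractor(build_model("DUSP16", "ERK"))
  expect_equal(classify_node_pattern(a16, "Survival"), "ON_THEN_OFF")
  expect_gt(a16$transient_length, 0)  # off after a finite transient
  expect_true(all(a16$cycle["Survival", ] == 0))
})

test_that("without Herceptin survival stays on where the stress kinases are controlled", {
  # untreated, HER2 signalling persists; in the DUSP1/2/4 models the DUSP
  # keeps JNK-and-p38 co-activation at bay and survival never drops
  for (id in c("DUSP1", "DUSP2", "DUSP4")) {
    att <- model_attractor(build_model(id), herceptin = 0L)
    expect_true(all(att$cycle["Survival", ] == 1), info = id)
  }
})

test_that("the DUSP inhibition edges are functionally live", {
  # dropping 'and not DUSP5' from ERK's rule destroys the oscillation
  m <- build_model("DUSP5")
  lines <- c("#input: Herceptin Basal",
             "HER2* = not Herceptin",
             "ERK* = (HER2 or Basal)",          # inhibition removed
             "JNK* = HER2", "p38* = HER2",
             "DUSP5* = ERK",
             "Survival* = ERK or not (JNK and p38)",
             "Herceptin = True", "Basal = True", "HER2 = False",
             "ERK = True", "JNK = False", "p38 = False",
             "DUSP5 = True", "Survival = True")
  ablated <- parse_rules(lines)
  att <- find_attractor(ablated)
  expect_false(classify_node_pattern(att, "ERK") == "OSCILLATING")
  expect_equal(classify_node_pattern(model_attractor(m), "ERK"),
               "OSCILLATING")
})

test_that("JNK and p38 are interchangeable in the DUSP9 and DUSP23 scaffolds", {
  for (id in c("DUSP9", "DUSP23")) {
    m <- build_model(id, "JNK")
    swap <- function(s) {
      s <- gsub("\\bJNK\\b", "@TMP@", s)
      s <- gsub("\\bp38\\b", "JNK", s)
      gsub("@TMP@", "p38", s, fixed = TRUE)
    }
    swapped_rules <- vapply(m$network$rule_text, swap, character(1))
    names(swapped_rules) <- swap(names(swapped_rules))
    m_p38 <- build_model(id, "p38")
    # rule-for-rule identity after relabelling; the survival gate is
    # syntactically fixed and already symmetric in JNK and p38
    keep <- setdiff(names(swapped_rules), "Survival")
    expect_mapequal(m_p38$network$rule_text[keep], swapped_rules[keep])
    expect_identical(m_p38$network$rule_text[["Survival"]],
                     m$network$rule_text[["Survival"]])
  }
})

test_that("shipped rule files equal the programmatically built models", {
  for (id in regulation_facts_table()$dusp) {
    file_net <- read_boolean_network(dusp_model_file(id))
    built <- duspboolnet:::default_model(id)$network
    expect_equal(file_net$rule_text, built$rule_text, info = id)
    expect_setequal(file_net$inputs, built$inputs)
    expect_mapequal(file_net$init, built$init)
  }
})
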