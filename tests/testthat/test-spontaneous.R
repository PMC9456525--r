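dc_test <- drug_class("gliptins", c("sitagliptin", "vildagliptin"))
ev_test <- event_definition("mi", c("Myocardial infarction"))

write_report_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("case_id\tdrug\trole\tevent_pt", lines), path)
  path
}

test_that("read_reports aggregates rows per case with set semantics", {
  path <- write_report_file(c(
    "c1\tsitagliptin\tsuspect\t",
    "c1\tvildagliptin\tconcomitant\t",
    "c1\t\t\tMyocardial infarction"))
  rs <- read_reports(path)
  expect_length(rs$case_ids, 1L)
  expect_equal(nrow(rs$drugs), 2L)
  expect_equal(nrow(rs$events), 1L)

  # duplicates collapse
  path2 <- write_report_file(rep("c1\tsitagliptin\tsuspect\tMyocardial infarction", 3))
  rs2 <- read_reports(path2)
  expect_equal(nrow(rs2$drugs), 1L)
  expect_equal(nrow(rs2$events), 1L)

  # empty file with header
  rs3 <- read_reports(write_report_file(character()))
  expect_length(rs3$case_ids, 0L)
})

test_that("read_reports rejects malformed input with line numbers", {
  path <- write_report_file(c(
    "c1\tsitagliptin\tsuspect\t",
    "c2\tsitagliptin\tprescribed\t"))  # bad role on file line 3
  expect_error(read_reports(path), "line\\(s\\): 3")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case_id\tdrug\trole", "c1\tx\tsuspect"), path2)
  expect_error(read_reports(path2), "event_pt")
})

test_that("write_reports round-trips through read_reports", {
  rs <- random_report_set(40, c("sitagliptin", "metformin", "aspirin"),
                          c("Myocardial infarction", "Nausea"), seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reports(rs, path)
  back <- read_reports(path)
  expect_equal(back$drugs, rs$drugs)
  expect_equal(back$events, rs$events)
  expect_equal(back$case_ids, rs$case_ids)
})

test_that("build_contingency counts cases, not rows, honouring suspect_only", {
  # 10 cases: 3 with the drug (suspect), 4 with the event, 2 joint
  drugs <- data.frame(
    case_id = c("c1", "c2", "c3", "c1"),
    drug = c("sitagliptin", "sitagliptin", "vildagliptin", "sitagliptin"),
    role = "suspect")
  events <- data.frame(case_id = c("c1", "c2", "c4", "c5"),
                       event_pt = "Myocardial infarction")
  rs <- compsafety:::report_set(drugs, events, sprintf("c%d", 1:10))
  tab <- build_contingency(rs, dc_test, ev_test)
  expect_equal(c(tab$n11, tab$n1dot, tab$ndot1, tab$ndotdot), c(2L, 3L, 4L, 10L))

  # same stream but the joint cases list the drug as concomitant
  drugs2 <- drugs
  drugs2$role[drugs2$case_id %in% c("c1", "c2")] <- "concomitant"
  rs2 <- compsafety:::report_set(drugs2, events, sprintf("c%d", 1:10))
  expect_equal(build_contingency(rs2, dc_test, ev_test)$n11, 0L)
  expect_equal(build_contingency(rs2, dc_test, ev_test, suspect_only = FALSE)$n11, 2L)
})

test_that("combination-product names are excluded from the class", {
  drugs <- data.frame(case_id = c("c1", "c2"),
                      drug = c("sitagliptin", "sitagliptin/metformin"),
                      role = "suspect")
  events <- data.frame(case_id = "c1", event_pt = "Myocardial infarction")
  rs <- compsafety:::report_set(drugs, events, c("c1", "c2"))
  dc <- drug_class("gliptins", c("sitagliptin", "sitagliptin/metformin"),
                   exclude_names = "sitagliptin/metformin")
  expect_equal(build_contingency(rs, dc, ev_test)$n1dot, 1L)
})

test_that("contingency matches a brute-force double loop on a synthetic stream", {
  cfg <- report_sim_config(5000, target_drug_share = 0.05,
                           target_event_share = 0.04, reporting_ratio = 2,
                           seed = 21)
  rs <- generate_spontaneous_reports(cfg)
  dc <- drug_class("target", cfg$target_drugs)
  ev <- event_definition("target_event", cfg$target_events)
  tab <- build_contingency(rs, dc, ev)
  oracle <- oracle_contingency(rs, dc, ev)
  expect_equal(c(tab$n11, tab$n1dot, tab$ndot1, tab$ndotdot),
               unname(oracle), ignore_attr = TRUE)
})

test_that("build_contingency is invariant under report-row permutations", {
  rs <- random_report_set(200, c("sitagliptin", "metformin"),
                          c("Myocardial infarction", "Cardiac failure"), seed = 8)
  perm <- compsafety:::with_seed(1, {
    compsafety:::report_set(
      rs$drugs[sample(nrow(rs$drugs)), ],
      rs$events[sample(nrow(rs$events)), ],
      sample(rs$case_ids))
  })
  t1 <- build_contingency(rs, dc_test, ev_test)
  t2 <- build_contingency(perm, dc_test, ev_test)
  expect_equal(t1, t2)
})

test_that("enumerate_pairs yields the Cartesian product with a shared total", {
  rs <- random_report_set(300, c("sitagliptin", "metformin", "aspirin"),
                          c("Myocardial infarction", "Cerebral infarction",
                            "Cardiac failure", "Nausea"), seed = 13)
  dcs <- list(drug_class("a", "sitagliptin"), drug_class("b", "metformin"))
  evs <- lapply(c("Myocardial infarction", "Cerebral infarction",
                  "Cardiac failure", "Nausea"),
                function(p) event_definition(p, p))
  pairs <- enumerate_pairs(rs, dcs, evs)
  expect_length(pairs, 8L)
  expect_true(all(vapply(pairs, function(p) p$table$ndotdot, 0L) == 300L))
  for (p in pairs) {
    dc <- dcs[[which(vapply(dcs, `[[`, "", "name") == p$drug)]]
    ev <- evs[[which(vapply(evs, `[[`, "", "name") == p$event)]]
    expect_equal(p$table, build_contingency(rs, dc, ev))
  }
})

test_that("composed event groups use set-union semantics", {
  mi <- event_definition("mi", "Myocardial infarction")
  stroke <- event_definition("stroke", "Cerebral infarction")
  mace <- event_definition("mace", composed_of = list(mi, stroke))
  rs <- random_report_set(400, c("sitagliptin", "metformin"),
                          c("Myocardial infarction", "Cerebral infarction",
                            "Nausea"), seed = 30)
  n_mace <- build_contingency(rs, dc_test, mace)$ndot1
  n_mi <- build_contingency(rs, dc_test, mi)$ndot1
  n_st <- build_contingency(rs, dc_test, stroke)$ndot1
  expect_lte(n_mace, n_mi + n_st)
  expect_gte(n_mace, max(n_mi, n_st))
})

test_that("contingency invariants are enforced", {
  expect_error(contingency_table(5, 3, 10, 100), "margin")
  expect_error(contingency_table(1, 2, 101, 100), "total")
  expect_error(contingency_table(0, 60, 60, 100), "exceed")
  expect_error(build_contingency(
    compsafety:::report_set(data.frame(case_id = character(), drug = character(),
                                       role = character()),
                            data.frame(case_id = character(), event_pt = character()),
                            character()),
    dc_test, ev_test), "empty")
})
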