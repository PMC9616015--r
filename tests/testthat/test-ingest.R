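test_that("threshold filter drops small organizations of targeted sectors only", {
  set.seed(1)
  # 162 specialized-care organizations with a clients attribute, thresholded
  # at 6, alongside untouched organizations of another sector
  clients <- c(rep(2, 68), rep(10, 94))   # exactly 94 meet the bound
  roster <- Roster(
    org_id = c(sprintf("spec%03d", 1:162), "edu1", "edu2"),
    sector = c(rep("specialized_youth_care", 162), "education", "education"),
    tasks = c(rep("providing_services", 162), "signaling", "signaling"),
    respondent_ids = c(sprintf("r%03d", 1:162), "re1", "re2"),
    attributes = data.frame(clients_2017 = c(clients, NA, NA)))
  out <- applyThresholdFilter(roster, "clients_2017", 6,
                              "specialized_youth_care")
  kept <- out@orgs
  expect_equal(sum(kept$sector == "specialized_youth_care"), 94)
  expect_equal(sum(kept$sector == "education"), 2)
})

test_that("threshold filter edge cases and errors", {
  roster <- tiny_roster(4)
  expect_identical(applyThresholdFilter(roster, "x", 0, "education")@orgs,
                   roster@orgs)
  expect_identical(applyThresholdFilter(roster, "x", 5, character())@orgs,
                   roster@orgs)
  # attribute missing for a targeted organization names the organization
  expect_error(applyThresholdFilter(roster, "clients", 5, "education"),
               "o01")
})

test_that("report validation rejects inconsistent records", {
  roster <- tiny_roster(3)
  ok <- data.frame(respondent_id = "o01_r1", reporter_org = "o01",
                   target_org = "o02", layer = "contact")
  expect_s4_class(TieReportSet(ok, roster), "TieReportSet")
  expect_error(TieReportSet(transform(ok, target_org = "ghost"), roster),
               "absent from the roster")
  expect_error(TieReportSet(transform(ok, target_org = "o01"), roster),
               "elf-report")
  expect_error(TieReportSet(transform(ok, layer = "friendship"), roster),
               "layer")
  expect_error(TieReportSet(transform(ok, respondent_id = "o02_r1"), roster),
               "not theirs")
})

test_that("collapsing ORs reports across respondents of an organization", {
  roster <- Roster(org_id = c("a", "b", "c"),
                   sector = rep("education", 3),
                   tasks = rep("signaling", 3),
                   respondent_ids = c("a1;a2", "b1", "c1"))
  rec <- data.frame(
    respondent_id = c("a1", "a2", "b1"),
    reporter_org = c("a", "a", "b"),
    target_org = c("b", "c", "a"),
    layer = "contact")
  rm <- collapseRespondents(roster, TieReportSet(rec, roster), "contact")
  m <- adjMatrix(rm)
  # one respondent reporting suffices (second respondent omitted a->b)
  expect_equal(m["a", "b"], 1L)
  expect_equal(m["a", "c"], 1L)
  expect_equal(m["b", "a"], 1L)
  expect_equal(sum(m), 3L)
  expect_true(all(responded(rm)[c("a", "b")]))
  expect_false(responded(rm)[["c"]])
  expect_true(all(m[!responded(rm), ] == 0))
})

test_that("collapse equals the brute-force OR oracle on random report sets", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    ids <- sprintf("o%02d", seq_len(n))
    roster <- Roster(org_id = ids, sector = rep("s", n),
                     tasks = rep("signaling", n),
                     respondent_ids = lapply(ids, function(i)
                       paste0(i, "_r", seq_len(sample(1:3, 1)))))
    rr <- rosterRespondents(roster)
    k <- sample(0:40, 1)
    pick <- rr[sample(nrow(rr), k, replace = TRUE), , drop = FALSE]
    tg <- vapply(pick$org_id, function(o) sample(setdiff(ids, o), 1), "")
    rec <- data.frame(respondent_id = pick$respondent_id,
                      reporter_org = pick$org_id, target_org = tg,
                      layer = sample(c("contact", "referral"), k,
                                     replace = TRUE))
    reports <- TieReportSet(rec, roster)
    for (layer in c("contact", "referral")) {
      rm <- collapseRespondents(roster, reports, layer)
      expect_identical(adjMatrix(rm), naive_collapse(rec, ids, layer))
      expect_true(all(adjMatrix(rm) %in% c(0L, 1L)))
      expect_true(all(rowSums(adjMatrix(rm)) <= n - 1))
    }
  }
})

test_that("collapse is idempotent and order-independent over respondents", {
  set.seed(13)
  roster <- Roster(org_id = c("a", "b", "c", "d"),
                   sector = rep("s", 4), tasks = rep("signaling", 4),
                   respondent_ids = c("a1;a2;a3", "b1", "c1;c2", "d1"))
  rec <- data.frame(
    respondent_id = c("a1", "a2", "a3", "c1", "c2"),
    reporter_org = c("a", "a", "a", "c", "c"),
    target_org = c("b", "b", "c", "a", "d"),
    layer = "contact")
  m1 <- adjMatrix(collapseRespondents(roster, TieReportSet(rec, roster),
                                      "contact"))
  shuffled <- rec[sample(nrow(rec)), ]
  m2 <- adjMatrix(collapseRespondents(roster, TieReportSet(shuffled, roster),
                                      "contact"))
  doubled <- rbind(rec, rec)
  m3 <- adjMatrix(collapseRespondents(roster, TieReportSet(doubled, roster),
                                      "contact"))
  expect_identical(m1, m2)
  expect_identical(m1, m3)
})

test_that("a separate responses register distinguishes all-negative response from nonresponse", {
  roster <- tiny_roster(3)
  reports <- TieReportSet(data.frame(respondent_id = "o01_r1",
                                     reporter_org = "o01",
                                     target_org = "o02", layer = "contact"),
                          roster)
  responses <- data.frame(respondent_id = c("o01_r1", "o02_r1"),
                          responded = c(1, 1))
  rm <- collapseRespondents(roster, reports, "contact", responses)
  # o02 responded but reported nothing: an all-negative response
  expect_true(responded(rm)[["o02"]])
  expect_false(responded(rm)[["o03"]])
  # records from a respondent marked nonresponding are inconsistent input
  bad <- data.frame(respondent_id = "o01_r1", responded = 0)
  expect_error(collapseRespondents(roster, reports, "contact", bad),
               "nonresponding")
  expect_error(collapseRespondents(roster, reports, "friendship"),
               "unknown layer")
})

test_that("referral collapse is a subset of contact collapse when reports are", {
  sv <- generateSurvey(syntheticConfig(n_orgs = 40L, seed = 31L))
  con <- collapseRespondents(sv$roster, sv$reports, "contact", sv$responses)
  ref <- collapseRespondents(sv$roster, sv$reports, "referral", sv$responses)
  expect_true(all(adjMatrix(ref) <= adjMatrix(con)))
})

test_that("roster, report and adjacency CSV round trips preserve content", {
  sv <- generateSurvey(syntheticConfig(n_orgs = 25L, seed = 8L))
  td <- withr::local_tempdir()
  rp <- file.path(td, "roster.csv")
  writeRoster(sv$roster, rp)
  expect_identical(readRoster(rp)@orgs$org_id, orgIds(sv$roster))
  expect_identical(readRoster(rp)@orgs$respondent_ids,
                   sv$roster@orgs$respondent_ids)
  tp <- file.path(td, "reports.csv")
  writeTieReports(sv$reports, tp)
  expect_identical(tieRecords(readTieReports(tp, sv$roster)),
                   tieRecords(sv$reports))
  ap <- file.path(td, "adj.csv")
  writeAdjacencyCSV(sv$truth@contact, ap)
  expect_identical(adjMatrix(readAdjacencyCSV(ap)), sv$truth@contact)
})
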