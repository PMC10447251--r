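# Compound matching, lipid-name curation, pathway ranking.

toy_db <- function() {
    data.frame(
        compound_name = c("PC(22:1(13Z)/20:0)", "PE(18:0/22:6)", "met_x",
                          "met_y"),
        monoisotopic_mass = c(841.7, 791.5, 300.2, 300.2005),
        formula = NA,
        pathway = c("Phosphatidylcholine Biosynthesis PC(22:1(13Z)/20:0)",
                    "Phosphatidylethanolamine Biosynthesis", "pathway_a",
                    "pathway_a"),
        subclass = c("PC biosynthesis", "PE biosynthesis", "misc", "misc"),
        stringsAsFactors = FALSE)
}

test_that("exact mass queries match with zero ppm error", {
    db <- toy_db()
    q <- 300.2 - 1.007276467
    hits <- matchIons(q, db, defaultAdducts("negative"), ppm_tol = 1)
    expect_equal(hits$compound_name, "met_x")
    expect_equal(hits$ppm_error, 0)
    expect_error(matchIons(q, db, defaultAdducts()[0, ]), "adduct")
})

test_that("the ppm tolerance boundary is inclusive", {
    # query 500.0025 against theoretical 500.0000 is exactly +5 ppm
    db <- data.frame(compound_name = "edge",
                     monoisotopic_mass = 500.0 + 1.007276467, formula = NA,
                     pathway = "p", subclass = "s")
    hits <- matchIons(500.0025, db, defaultAdducts("negative"), ppm_tol = 5)
    expect_equal(nrow(hits), 1)
    expect_equal(hits$ppm_error, 5, tolerance = 1e-6)
    none <- matchIons(500.0030, db, defaultAdducts("negative"), ppm_tol = 5)
    expect_equal(nrow(none), 0)
})

test_that("ion matching equals the all-pairs brute-force scan", {
    add <- defaultAdducts("negative")
    withr::with_seed(123, {
        for (i in 1:40) {
            n_db <- sample(3:20, 1)
            masses <- runif(n_db, 100, 900)
            names_db <- sprintf("c%02d", seq_len(n_db))
            db <- data.frame(compound_name = names_db,
                             monoisotopic_mass = masses, formula = NA,
                             pathway = "p", subclass = "s")
            # queries clustered near true ion m/z so hits actually occur
            q <- (sample(masses, 5, replace = TRUE) - 1.007276467) *
                (1 + runif(5, -8e-6, 8e-6))
            got <- matchIons(q, db, add, ppm_tol = 5)
            want <- match_oracle(q, masses, names_db, add$shift, add$adduct, 5)
            if (is.null(want)) {
                expect_equal(nrow(got), 0)
            } else {
                key <- function(d) sort(paste(d$query_mz, d$adduct,
                                              d$compound_name))
                expect_equal(key(got), key(want))
                expect_equal(sort(got$ppm_error), sort(want$ppm_error),
                             tolerance = 1e-9)
            }
        }
    })
})

test_that("lipid names shorten to sum compositions and are idempotent", {
    expect_equal(shortenLipidName("PC(22:1(13Z)/20:0)"), "PC(42:1)")
    expect_equal(shortenLipidName("PC(42:1)"), "PC(42:1)")
    expect_equal(shortenLipidName("PE(18:0/22:6(4Z,7Z,10Z,13Z,16Z,19Z))"),
                 "PE(40:6)")
    expect_equal(
        shortenLipidName("Phosphatidylcholine Biosynthesis PC(22:1(13Z)/20:0)"),
        "Phosphatidylcholine Biosynthesis PC(42:1)")
    expect_equal(shortenLipidName("TG(16:0/18:1/18:2)"), "TG(52:3)")
    expect_equal(shortenLipidName("citrate cycle (TCA)"),
                 "citrate cycle (TCA)")
    expect_equal(shortenLipidName(shortenLipidName("PS(18:0/20:4(5Z,8Z,11Z,14Z))")),
                 shortenLipidName("PS(18:0/20:4(5Z,8Z,11Z,14Z))"))
    expect_error(shortenLipidName("PC(22:1/x0)"), "malformed")
})

test_that("pathway ranking counts unique discriminating ions", {
    expect_equal(nrow(rankPathways(matchIons(numeric(0), toy_db()))), 0)

    mk <- function(q, pw, sub = "s") data.frame(
        query_mz = q, adduct = "[M-H]-", compound_name = paste0("c", q),
        theoretical_mz = q, ppm_error = 0,
        pathways = I(list(data.frame(pathway = pw, subclass = sub))))
    matches <- rbind(mk(1, "A"), mk(2, "A"), mk(3, "A"),
                     mk(4, "C"), mk(5, "C"),
                     mk(6, "B"), mk(7, "B"))
    r <- rankPathways(matches)
    expect_equal(r$pathway, c("A", "B", "C"))  # B before C on the tie
    expect_equal(r$n_unique_mz, c(3, 2, 2))

    # one query hitting two compounds of the same pathway counts once
    dup <- rbind(mk(9, "A"), mk(9, "A"))
    expect_equal(rankPathways(dup)$n_unique_mz, 1)
})

test_that("subclass curation merges collapsing names and never adds rows", {
    mk <- function(q, pw, sub) data.frame(
        query_mz = q, adduct = "[M-H]-", compound_name = paste0("c", q),
        theoretical_mz = q, ppm_error = 0,
        pathways = I(list(data.frame(pathway = pw, subclass = sub))))
    matches <- rbind(
        mk(1, "PC Biosynthesis PC(22:1(13Z)/20:0)", "pc"),
        mk(2, "PC Biosynthesis PC(22:0/20:1)", "pc"),   # same sum composition
        mk(3, "PC Biosynthesis PC(22:0/24:0)", "pc"))
    r <- rankPathways(matches)
    expect_equal(nrow(r), 2)  # 42:1 pair merged, 46:0 separate
    expect_equal(r$n_unique_mz[r$pathway == "PC Biosynthesis PC(42:1)"], 2)
    n_uncurated <- length(unique(c("PC Biosynthesis PC(22:1(13Z)/20:0)",
                                   "PC Biosynthesis PC(22:0/20:1)",
                                   "PC Biosynthesis PC(22:0/24:0)")))
    expect_lte(nrow(r), n_uncurated)
    expect_true(all(r$n_unique_mz <= length(unique(matches$query_mz))))
})
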