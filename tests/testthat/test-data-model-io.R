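test_that("MethylationExperiment validity enforces the data contract", {
    vals <- matrix(runif(6), 2, 3)
    me <- MethylationExperiment(vals, ages = c(1, 2, 3))
    expect_s4_class(me, "MethylationExperiment")
    expect_identical(dim(me), c(2L, 3L))
    expect_equal(unname(ages(me)), c(1, 2, 3))

    expect_error(MethylationExperiment(matrix(c(1, NA, 2, 3), 2, 2)),
                 "missing")
    expect_error(MethylationExperiment(matrix(1:2, 2, 1)),
                 "two individuals")
    expect_error(MethylationExperiment(vals, siteIds = c("a", "a")),
                 "unique")
    expect_error(MethylationExperiment(vals, ages = c(1, NA, 3)), "age")
    ## named ages are aligned, missing individuals are an error
    me2 <- MethylationExperiment(vals, individualIds = c("x", "y", "z"),
                                 ages = c(z = 3, x = 1, y = 2))
    expect_equal(unname(ages(me2)), c(1, 2, 3))
    expect_error(MethylationExperiment(vals, individualIds = c("x", "y", "z"),
                                       ages = c(x = 1, y = 2)), "missing")
})

test_that("matrix round-trips through delimited text bit-stably, both orientations", {
    set.seed(42)
    sim <- simulateMC(n = 7, m = 5, sigma = 0.05, seed = 42)
    for (ext in c("tsv", "csv")) {
        paths <- writeTempInput(sim, ext = ext)
        back <- readMethylationMatrix(paths$matrix)
        expect_identical(methLevels(back), methLevels(sim$experiment))
        expect_identical(rownames(back), rownames(sim$experiment))
        ## write transposed, read with the orientation flag: same canonical form
        tpath <- tempfile(fileext = paste0(".", ext))
        transposed <- t(methLevels(sim$experiment))
        out <- cbind(individual_id = rownames(transposed),
                     as.data.frame(formatC(transposed, digits = 17,
                                           format = "g"),
                                   check.names = FALSE, optional = TRUE))
        utils::write.table(out, tpath, sep = if (ext == "csv") "," else "\t",
                           quote = FALSE, row.names = FALSE)
        back2 <- readMethylationMatrix(tpath,
                                       orientation = "individuals_by_sites")
        expect_identical(methLevels(back2), methLevels(sim$experiment))
    }
})

test_that("malformed matrix files are rejected with the offending cell named", {
    path <- tempfile(fileext = ".tsv")
    writeLines(c("site_id\tA\tB", "s1\t0.1\t0.2", "s2\t\t0.4"), path)
    expect_error(readMethylationMatrix(path), "row 's2', column 'A'")

    writeLines(c("site_id\tA\tB", "s1\t0.1\toops", "s2\t0.3\t0.4"), path)
    expect_error(readMethylationMatrix(path), "non-numeric.*'oops'")

    writeLines(c("site_id\tA\tA", "s1\t0.1\t0.2", "s2\t0.3\t0.4"), path)
    expect_error(readMethylationMatrix(path), "duplicate column")

    writeLines(c("site_id\tA\tB", "s1\t0.1\t0.2", "s1\t0.3\t0.4"), path)
    expect_error(readMethylationMatrix(path), "duplicate row")
})

test_that("readAges aligns, errors on missing ids and warns on extras", {
    sim <- simulateMC(n = 3, m = 4, sigma = 0, seed = 5)
    me <- sim$experiment
    path <- tempfile(fileext = ".tsv")
    a <- ages(me)

    ## shuffled order is realigned to matrix column order
    shuffled <- sample(names(a))
    writeLines(c("individual_id\tage",
                 paste(shuffled, a[shuffled], sep = "\t")), path)
    got <- readAges(path, me)
    expect_equal(got, a, tolerance = 1e-12)
    expect_identical(names(got), colnames(me))

    ## one matrix individual absent -> error naming it
    writeLines(c("individual_id\tage",
                 paste(names(a)[-2], a[-2], sep = "\t")), path)
    expect_error(readAges(path, me), names(a)[2], fixed = TRUE)

    ## an extra individual is dropped with a warning, length stays m
    writeLines(c("individual_id\tage",
                 paste(c(names(a), "ghost"), c(a, 99), sep = "\t")), path)
    expect_warning(got <- readAges(path, me), "ghost")
    expect_length(got, ncol(me))

    ## duplicate id -> error
    writeLines(c("individual_id\tage",
                 paste(c(names(a), names(a)[1]), c(a, 1), sep = "\t")), path)
    expect_error(readAges(path, me), "duplicate")
})
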