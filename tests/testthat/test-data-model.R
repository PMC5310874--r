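# Core data types, validation and external formats.

test_that("study dimensions validate and derive the cohort count", {
  d <- study_dims(G = 2, A = 50, I = 13, T = 24, M = 5)
  expect_equal(d$K, 84)
  expect_equal(study_dims(2, 1, 2, 2, M = 5)$K, 7)
  expect_error(study_dims(0, 1, 2, 2), "G >= 1")
  expect_error(study_dims(1, 1, 1, 2), "age groups")
  expect_error(study_dims(1, 1, 2, 2, M = 0), "M >= 1")
  expect_error(study_dims(1.5, 1, 2, 2), "integers")
})

test_that("count tables load, validate completeness and round-trip", {
  path <- tiny_counts_file()
  ds <- load_counts(path)
  expect_equal(unclass(ds$dims)[c("G", "A", "I", "T")],
               list(G = 2L, A = 1L, I = 2L, T = 2L))
  expect_equal(ds$dims$K, 7)  # M = 5
  expect_equal(ds$deaths, tiny_dataset()$deaths)
  expect_equal(ds$population, tiny_dataset()$population)

  # tab-separated dialect autodetects
  path_tab <- tiny_counts_file(sep = "\t")
  expect_equal(load_counts(path_tab)$deaths, ds$deaths)

  # deleting a row is an error naming the missing cell
  tab <- utils::read.csv(path)
  short <- file.path(tempdir(), "short.csv")
  utils::write.csv(tab[-3, ], short, row.names = FALSE)
  expect_error(load_counts(short), "missing cell.*male.*1990")

  # duplicated cell
  dup <- file.path(tempdir(), "dup.csv")
  utils::write.csv(rbind(tab, tab[1, ]), dup, row.names = FALSE)
  expect_error(load_counts(dup), "duplicate cell")

  # negative deaths / nonpositive population name offending rows
  bad <- tab; bad$deaths[2] <- -1
  badf <- file.path(tempdir(), "bad.csv")
  utils::write.csv(bad, badf, row.names = FALSE)
  expect_error(load_counts(badf), "negative or non-integer deaths")
  bad <- tab; bad$population[4] <- 0
  utils::write.csv(bad, badf, row.names = FALSE)
  expect_error(load_counts(badf), "non-positive population")

  # missing column is a schema error
  nocol <- tab[, setdiff(names(tab), "population")]
  utils::write.csv(nocol, badf, row.names = FALSE)
  expect_error(load_counts(badf), "schema error.*population")
})

test_that("zero deaths are legitimate but zero population never is", {
  ds <- tiny_dataset()
  expect_equal(min(ds$deaths), 0)
  pop <- ds$population; pop[1] <- 0
  expect_error(
    mortality_dataset(ds$deaths, pop, ds$labels),
    "strictly positive"
  )
})

test_that("the national table fixture matches its printed values", {
  tab <- table1_fixture()
  expect_equal(dim(tab$deaths), c(2, 1, 13, 1))
  # spot values
  expect_equal(tab$deaths[1, 1, 1, 1], 29)        # female [25,30)
  expect_equal(tab$population[2, 1, 13, 1], 5711393)  # male [85,+)
  # column totals
  expect_equal(sum(tab$deaths[1, , , ]), 48346)
  expect_equal(sum(tab$deaths[2, , , ]), 54652)
  expect_equal(sum(tab$population[1, , , ]), 369126507)
  expect_equal(sum(tab$population[2, , , ]), 343698536)
  expect_equal(sum(tab$deaths), 102998)
})

test_that("graphs load from both dialects with symmetric neighbours", {
  dir <- withr::local_tempdir()
  # edge list: path on 3 nodes
  f <- file.path(dir, "p3.edges")
  writeLines(c("1 2", "2 3"), f)
  g <- load_graph(f)
  expect_equal(g$n, 3)
  expect_equal(g$n_components, 1)

  # two disjoint edges -> 2 components
  writeLines(c("1 2", "3 4"), f)
  expect_equal(load_graph(f)$n_components, 2)

  # region dialect round-trips the lattice
  lat <- lattice_graph(5, 10)
  expect_equal(lat$n, 50)
  expect_equal(nrow(lat$edges), 85)   # 2rc - r - c
  rf <- file.path(dir, "lat.graph")
  write_graph(lat, rf, format = "region")
  lat2 <- load_graph(rf)
  expect_equal(lat2$edges, lat$edges)
  ef <- file.path(dir, "lat.edges")
  write_graph(lat, ef, format = "edges")
  expect_equal(load_graph(ef)$edges, lat$edges)

  # symmetry: a neighbours b iff b neighbours a (via the adjacency matrix)
  W <- matrix(0, lat$n, lat$n)
  W[lat$edges] <- 1; W[lat$edges[, 2:1]] <- 1
  expect_identical(W, t(W))

  # errors
  writeLines("1 1", f)
  expect_error(load_graph(f), "self-loop")
  writeLines(c("n 3", "1 7"), f)
  expect_error(load_graph(f), "unknown node")
})

test_that("standard populations validate and the shipped ESP weights align", {
  sp <- standard_population(c("[25,30)", "[30,35)"), c(2, 6))
  expect_equal(sp$weight_norm, c(0.25, 0.75))
  expect_error(standard_population("[25,30)", -1), "non-negative")
  esp <- esp2013_standard()
  expect_equal(nrow(esp), 13)
  expect_equal(sum(esp$weight), 72500)  # ages 25+ share of the ESP 2013
  expect_setequal(esp$age_group, table1_fixture()$labels$age_group)
})
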