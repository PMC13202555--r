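test_that("carrying rate counts carrier contigs over all contigs", {
  contigs <- make_contigs("S", 10)
  hits <- rbind(
    make_hit("S", "S_c0001", "ARG", "g1"),
    make_hit("S", "S_c0001", "ARG", "g2"),  # same contig, still 1 carrier
    make_hit("S", "S_c0002", "MRG", "g3")
  )
  set <- build_sample_set(contigs, hits)
  expect_equal(as.numeric(carrying_rate(set, "ARG")), 0.1)
  expect_equal(as.numeric(carrying_rate(set, "MRG")), 0.1)
  expect_equal(as.numeric(carrying_rate(set, "VFG")), 0)
})

test_that("zero contigs is an error, not a zero rate", {
  set <- list(sample_id = "S", contigs = make_contigs("S", 1)[0, ],
              hits = empty_hits_df())
  class(set) <- "sample_set"
  expect_error(carrying_rate(set, "ARG"), "zero contigs")
  expect_error(cooccurrence_rate(set, c("ARG", "MRG")), "zero contigs")
})

test_that("co-occurrence requires every class in the subset on one contig", {
  contigs <- make_contigs("S", 10)
  hits <- rbind(
    make_hit("S", "S_c0001", "ARG", "g1"),
    make_hit("S", "S_c0001", "MRG", "g2"),
    make_hit("S", "S_c0002", "VFG", "g3")
  )
  set <- build_sample_set(contigs, hits)
  expect_equal(as.numeric(cooccurrence_rate(set, c("ARG", "MRG"))), 0.1)
  expect_equal(as.numeric(cooccurrence_rate(set, c("ARG", "VFG"))), 0)
  expect_equal(as.numeric(cooccurrence_rate(set, c("MRG", "ARG", "VFG"))), 0)
  expect_equal(as.numeric(cooccurrence_rate(set, "any_pair")), 0.1)
  expect_error(cooccurrence_rate(set, "ARG"), "at least two")
})

test_that("mobility potential is a per-gene ratio with undefined 0/0", {
  contigs <- make_contigs("S", 10)
  hits <- rbind(
    make_hit("S", "S_c0001", "ARG", "g1"),
    make_hit("S", "S_c0002", "ARG", "g2"),
    make_hit("S", "S_c0003", "ARG", "g3"),
    make_hit("S", "S_c0004", "ARG", "g4"),
    make_hit("S", "S_c0001", "MGE", "tnpA", subclass = "transposon")
  )
  set <- build_sample_set(contigs, hits)
  expect_equal(as.numeric(mobility_potential(set, "ARG", "transposon")), 0.25)
  expect_equal(as.numeric(mobility_potential(set, "ARG", "overall")), 0.25)
  expect_equal(as.numeric(mobility_potential(set, "ARG", "integron")), 0)
  expect_true(is.na(mobility_potential(set, "VFG")))  # 0/0 is missing
})

test_that("plasmid/phage context labels feed the context-mediated MP", {
  contigs <- make_contigs("S", 4,
                          contexts = c("plasmid", "phage",
                                       "chromosome-like", "unknown"))
  hits <- rbind(
    make_hit("S", "S_c0001", "MRG", "g1"),
    make_hit("S", "S_c0002", "MRG", "g2"),
    make_hit("S", "S_c0003", "MRG", "g3"),
    make_hit("S", "S_c0004", "MRG", "g4")
  )
  set <- build_sample_set(contigs, hits)
  expect_equal(as.numeric(mobility_potential(set, "MRG", "plasmid")), 0.25)
  expect_equal(as.numeric(mobility_potential(set, "MRG", "phage")), 0.25)
  expect_equal(as.numeric(mobility_potential(set, "MRG", "overall")), 0.5)
})

test_that("indices equal brute-force contig scans on randomized fixtures", {
  set.seed(2024)
  for (rep in 1:50) {
    set <- random_sample_set(n_contigs = sample(20:60, 1),
                             n_hits = sample(10:80, 1))
    for (cl in c("MRG", "ARG", "VFG")) {
      expect_identical(as.numeric(carrying_rate(set, cl)),
                       oracle_cr(set, cl))
    }
    expect_identical(as.numeric(cooccurrence_rate(set, c("ARG", "MRG"))),
                     oracle_cor(set, c("ARG", "MRG")))
    expect_identical(as.numeric(cooccurrence_rate(set, "any_pair")),
                     oracle_cor(set, "any_pair"))
    for (cat in c("overall", "plasmid", "phage", "IS", "transposon",
                  "integron", "ICE")) {
      got <- mobility_potential(set, "ARG", cat)
      expect_identical(as.numeric(got), oracle_mp(set, "ARG", cat))
    }
  }
})

test_that("index invariants hold on random fixtures", {
  set.seed(55)
  for (rep in 1:20) {
    set <- random_sample_set(40, 50)
    crs <- sapply(c("MRG", "ARG", "VFG"),
                  function(cl) as.numeric(carrying_rate(set, cl)))
    for (pair in list(c("MRG", "ARG"), c("ARG", "VFG"), c("MRG", "VFG"))) {
      cor_p <- as.numeric(cooccurrence_rate(set, pair))
      expect_lte(cor_p, min(crs[pair]))
      expect_gte(cor_p, 0)
    }
    expect_lte(as.numeric(cooccurrence_rate(set, c("MRG", "ARG", "VFG"))),
               as.numeric(cooccurrence_rate(set, c("MRG", "ARG"))))
    for (cat in c("plasmid", "phage", "IS", "transposon", "integron",
                  "ICE")) {
      mp_c <- mobility_potential(set, "MRG", cat)
      mp_o <- mobility_potential(set, "MRG", "overall")
      if (!is.na(mp_c)) expect_lte(as.numeric(mp_c), as.numeric(mp_o))
    }
  }
})

test_that("adding an empty contig dilutes CR and CoR but not MP", {
  set.seed(9)
  set <- random_sample_set(30, 50)
  extra <- rbind(set$contigs,
                 make_contigs(set$sample_id, 1))
  extra$contig_id[nrow(extra)] <- "fresh_contig"
  grown <- build_sample_set(extra, set$hits)
  expect_lt(as.numeric(carrying_rate(grown, "ARG")),
            as.numeric(carrying_rate(set, "ARG")) + 1e-15)
  expect_equal(as.numeric(mobility_potential(grown, "ARG")),
               as.numeric(mobility_potential(set, "ARG")))
})

test_that("rate differences are exact rationals at the 100k-contig scale", {
  n <- 100000L
  contigs <- data.frame(sample_id = "S",
                        contig_id = paste0("c", seq_len(n)),
                        length_bp = 1000L,
                        mobility_context = "chromosome-like",
                        stringsAsFactors = FALSE)
  k <- 12345L
  hits_k <- make_hit("S", paste0("c", seq_len(k)), "ARG",
                     paste0("g", seq_len(k)))
  set_k <- build_sample_set(contigs, hits_k)
  hits_k1 <- make_hit("S", paste0("c", seq_len(k + 1L)), "ARG",
                      paste0("g", seq_len(k + 1L)))
  set_k1 <- build_sample_set(contigs, hits_k1)
  expect_identical(rate_delta(carrying_rate(set_k, "ARG"),
                              carrying_rate(set_k1, "ARG")), 1e-5)
  expect_error(rate_delta(1, 2), "mobindex rates")
})

test_that("index_table is complete, deterministic and order-invariant", {
  set.seed(123)
  sets <- lapply(sprintf("S%02d", 1:12), function(id) {
    random_sample_set(30, 40, sample_id = id)
  })
  names(sets) <- sprintf("S%02d", 1:12)
  tbl <- index_table(sets)
  expect_equal(nrow(tbl), 12)
  expect_true(all(c("cr_mrg", "cr_arg", "cr_vfg", "cor_arg_mrg",
                    "cor_all3", "mp_mrg", "mp_arg", "mp_vfg",
                    "mp_arg_transposon", "n_contigs") %in% names(tbl)))
  shuffled <- index_table(sets[sample(12)])
  expect_equal(shuffled, tbl)
  single <- index_table(sets[1])
  expect_equal(single$cr_arg,
               as.numeric(carrying_rate(sets[[1]], "ARG")))
})

test_that("indices TSV writes missing MP as empty fields", {
  contigs <- make_contigs("S01", 5)
  hits <- make_hit("S01", "S01_c0001", "ARG", "g1")
  tbl <- index_table(list(S01 = build_sample_set(contigs, hits)))
  expect_true(is.na(tbl$mp_mrg))
  path <- tempfile()
  write_indices(tbl, path)
  line <- strsplit(readLines(path)[2], "\t")[[1]]
  mp_col <- which(strsplit(readLines(path)[1], "\t")[[1]] == "mp_mrg")
  expect_identical(line[mp_col], "")
})
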