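test_that("E-value filter is strict, order-preserving and monotone", {
  hits <- data.frame(query_id = "q1", subject_id = c("s1", "s2", "s3"),
                     percent_identity = 99, alignment_length = 300,
                     evalue = c(1e-20, 1e-11, 1e-5),
                     bitscore = c(300, 200, 100))
  kept <- filter_hits_by_evalue(hits)
  expect_equal(kept$subject_id, "s1")        # 1e-11 removed: strict bound
  expect_equal(nrow(filter_hits_by_evalue(hits[0, ])), 0)
  expect_error(filter_hits_by_evalue(hits, -1), "non-negative")
  # monotone in the threshold
  for (t1 in c(1e-15, 1e-11, 1e-6)) {
    for (t2 in c(1e-15, 1e-11, 1e-6)) {
      if (t1 > t2) next
      expect_true(all(filter_hits_by_evalue(hits, t1)$subject_id %in%
                        filter_hits_by_evalue(hits, t2)$subject_id))
    }
  }
})

test_that("best hit maximizes bitscore with deterministic tie-breaks", {
  h <- function(s, bs, ev) data.frame(query_id = "q", subject_id = s,
                                      percent_identity = 98,
                                      alignment_length = 250,
                                      evalue = ev, bitscore = bs)
  two <- rbind(h("a", 300, 1e-30), h("b", 280, 1e-40))
  expect_equal(best_hit(two)$subject_id, "a")
  expect_equal(best_hit(two[1, ])$subject_id, "a")
  tie <- rbind(h("a", 300, 1e-20), h("b", 300, 1e-30))
  expect_equal(best_hit(tie)$subject_id, "b")   # lower evalue wins
  tie2 <- rbind(h("zzz", 300, 1e-30), h("aaa", 300, 1e-30))
  expect_equal(best_hit(tie2)$subject_id, "aaa") # lexicographic
  expect_null(best_hit(NULL))
  mixed <- rbind(h("a", 300, 1e-30), h("b", 280, 1e-40))
  mixed$query_id <- c("q1", "q2")
  expect_error(best_hit(mixed), "single query")
})

test_that("best characterized hit restricts to characterized subjects", {
  hits <- data.frame(query_id = "q", subject_id = c("a", "b", "c"),
                     percent_identity = 98, alignment_length = 250,
                     evalue = c(1e-50, 1e-40, 1e-30),
                     bitscore = c(400, 350, 300))
  ref <- data.frame(protein_id = c("a", "b", "c"), family = "GH3",
                    characterized = c(FALSE, FALSE, TRUE),
                    structure_known = FALSE)
  expect_equal(best_characterized_hit(hits, ref)$subject_id, "c")
  ref$characterized <- FALSE
  expect_null(best_characterized_hit(hits, ref))
  ref$characterized <- c(FALSE, TRUE, TRUE)
  expect_equal(best_characterized_hit(hits, ref)$subject_id, "b")
  expect_error(best_characterized_hit(hits, ref[-1, ]),
               "missing from reference")
})

test_that("confident membership applies the 97/200 rule with its exact boundary", {
  h <- function(id, len) data.frame(query_id = "q", subject_id = "s",
                                    percent_identity = id,
                                    alignment_length = len,
                                    evalue = 1e-30, bitscore = 100)
  expect_true(is_confident_member(h(98, 250)))
  expect_false(is_confident_member(h(97, 200)))  # length must exceed 200
  expect_true(is_confident_member(h(97, 201)))
  expect_false(is_confident_member(h(96.9, 500)))
  # monotone non-decreasing in identity and length
  grid <- expand.grid(id = c(95, 97, 99), len = c(150, 201, 400))
  val <- mapply(function(i, l) is_confident_member(h(i, l)),
                grid$id, grid$len)
  for (a in seq_len(nrow(grid)))
    for (b in seq_len(nrow(grid)))
      if (grid$id[a] <= grid$id[b] && grid$len[a] <= grid$len[b])
        expect_true(val[a] <= val[b])
})

test_that("cluster acceptance uses means over members with hits", {
  bh <- data.frame(protein_id = c("g1", "g2", "g3"),
                   percent_identity = c(100, 100, NA),
                   alignment_length = c(400, 400, NA))
  expect_true(cluster_acceptance(c("g1", "g2", "g3"), bh))
  expect_false(cluster_acceptance("g4", bh))   # no member has a hit
  # raising the boundary never converts rejected to accepted
  for (i0 in c(20, 40, 60, 101)) {
    lo <- cluster_acceptance(c("g1", "g2"), bh, identity_min = i0)
    hi <- cluster_acceptance(c("g1", "g2"), bh, identity_min = i0 + 10)
    expect_true(hi <= lo)
  }
})

test_that("majority vote picks the modal family with audit of tie-breaks", {
  v <- data.frame(gene_id = paste0("g", 1:7),
                  family = c(rep("GH3", 5), rep("GH1", 2)),
                  bitscore = 100)
  fc <- majority_vote_family(v, "c1")
  expect_equal(fc$family, "GH3")
  expect_false(fc$tie_broken)
  expect_equal(unname(fc$tally[c("GH3", "GH1")]), c(5L, 2L))
  # tie broken by summed bitscore
  v2 <- data.frame(gene_id = paste0("g", 1:4),
                   family = c("GH5", "GH5", "GH45", "GH45"),
                   bitscore = c(150, 150, 140, 140))
  fc2 <- majority_vote_family(v2)
  expect_equal(fc2$family, "GH5")
  expect_true(fc2$tie_broken)
  # then lexicographic on the label
  v3 <- data.frame(gene_id = paste0("g", 1:2),
                   family = c("GH45", "GH5"), bitscore = c(10, 10))
  expect_equal(majority_vote_family(v3)$family, "GH45")
  # no voting members -> UNASSIGNED (bare-class rows of the curated table)
  expect_equal(majority_vote_family(NULL, "c0")$family, "UNASSIGNED")
  # invariant under member permutation
  set.seed(42)
  for (i in 1:10) {
    perm <- v[sample(nrow(v)), ]
    expect_equal(majority_vote_family(perm)$family, "GH3")
  }
})

test_that("BLAST tabular files round-trip through the reader", {
  h <- gen_hit_table(20, 0.5, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(h$hits, path)
  back <- read_blast_tab(path)
  expect_equal(back$query_id, h$hits$query_id)
  expect_equal(back$percent_identity, h$hits$percent_identity)
  expect_equal(back$evalue, h$hits$evalue, tolerance = 1e-6)
  # reader tolerates extra trailing columns
  lines <- readLines(path)
  writeLines(paste0(lines, "\textra\t42"), path)
  expect_equal(read_blast_tab(path)$bitscore, back$bitscore)
})

test_that("membership calls on synthetic truth are exact", {
  for (sd in c(1, 2)) {
    for (mf in c(0, 0.5, 1)) {
      h <- gen_hit_table(60, mf, seed = sd)
      mc <- membership_calls(h$hits)
      got <- mc$is_cazyme[match(h$truth$query_id, mc$protein_id)]
      expect_identical(got, h$truth$is_member)
    }
  }
})
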