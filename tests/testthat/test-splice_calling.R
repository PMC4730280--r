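aln_row <- function(read_id, b1, b2 = NULL, mate = 1L) {
  tibble::tibble(
    read_id = read_id, mate = mate, strand = "+", mismatches = 0L,
    n_blocks = if (is.null(b2)) 1L else 2L,
    start1 = b1[1], end1 = b1[2], rstart1 = 0L,
    start2 = if (is.null(b2)) NA_integer_ else b2[1],
    end2 = if (is.null(b2)) NA_integer_ else b2[2],
    rstart2 = if (is.null(b2)) NA_integer_ else b1[2] - b1[1]
  )
}

test_that("junction calling enforces the GT-AG rule and support floor", {
  #             0123456789012345678901234567890
  ref <- paste0("AAAACCCCTT", "GTAAAAAG", "TTCCCCAAAA") # GT..AG at [10,18)
  good <- dplyr::bind_rows(
    aln_row("r1", c(2L, 10L), c(18L, 26L)),
    aln_row("r2", c(3L, 10L), c(18L, 27L))
  )
  jx <- call_introns(good, ref, min_support = 2L)
  expect_equal(as.data.frame(jx),
               data.frame(donor = 10L, acceptor = 18L, length = 8L,
                          support = 2L))
  # support below the floor is not called
  expect_equal(nrow(call_introns(good[1, ], ref, min_support = 2L)), 0L)
  # a GC..AG skip is rejected
  ref_gc <- ref
  substr(ref_gc, 12, 12) <- "C"
  expect_equal(nrow(call_introns(good, ref_gc, min_support = 1L)), 0L)
})

test_that("classification reports alternative sites as signed offsets", {
  g <- fx_cuzn()
  i2 <- g$introns[2, ]
  # junction evidence: canonical I2 plus an acceptor shifted +6
  jx <- dplyr::bind_rows(
    tibble::tibble(donor = i2$start, acceptor = i2$end, length = 76L,
                   support = 20L),
    tibble::tibble(donor = i2$start, acceptor = i2$end + 6L, length = 82L,
                   support = 3L)
  )
  cat2 <- classify_events(jx, aln_row("x", c(0L, 8L)), g)
  sub <- cat2[cat2$intron == "I2", ]
  expect_setequal(sub$type, c("canonical", "alt3"))
  expect_equal(sub$offset[sub$type == "alt3"], 6L)
})

test_that("only-canonical evidence yields only canonical states", {
  g <- fx_mn1()
  mix <- tibble::tibble(isoform = "canonical", prop = 1,
                        states = list(rep("canonical", 3)))
  reads <- simulate_read_pairs(g, mix,
                               sim_config(coverage = 30, error_rate = 0.005,
                                          seed = 4))
  aln <- map_reads(reads, g$seq)
  cat2 <- classify_events(call_introns(aln, g$seq), aln, g)
  expect_equal(sort(unique(cat2$type)), "canonical")
})

test_that("novel junctions sharing neither end are reported, not classified", {
  g <- fx_mn1()
  jx <- tibble::tibble(donor = 5L, acceptor = 15L, length = 10L,
                       support = 4L)
  cat2 <- classify_events(jx, aln_row("x", c(0L, 8L)), g)
  expect_false(any(cat2$support > 0 & cat2$type != "canonical"))
  expect_equal(nrow(attr(cat2, "novel")), 1L)
})

test_that("annotation builds n+1 exons and rejects overlapping introns", {
  g <- fx_cuzn()
  catalog <- tibble::tibble(
    intron = g$introns$intron, start = g$introns$start, end = g$introns$end,
    type = "canonical", offset = 0L, support = 10L
  )
  bounds <- list(tss = 0L, tes = nchar(g$seq))
  m <- annotate_model(catalog, bounds, g$seq, gene_id = g$gene_id)
  expect_equal(nrow(model_exons(m)), 9L)
  expect_equal(m$introns, g$introns)

  none <- annotate_model(catalog[0, ], bounds, g$seq)
  expect_equal(model_exons(none),
               tibble::tibble(start = 0L, end = nchar(g$seq)))

  bad <- dplyr::bind_rows(
    catalog[1, ],
    dplyr::mutate(catalog[1, ], intron = "I1b", start = start + 10L,
                  end = end + 10L)
  )
  expect_error(annotate_model(bad, bounds, g$seq),
               class = "sod_ambiguity_error")
})

test_that("the closed loop recovers the generating model from reads", {
  g <- fx_mn1()
  reads <- simulate_read_pairs(
    g, config = sim_config(coverage = 150, error_rate = 0, seed = 6)
  )
  aln <- map_reads(reads, g$seq)
  jx <- call_introns(aln, g$seq)
  bounds <- determine_bounds(aln)
  canon <- infer_canonical_model(jx, bounds, g$seq, gene_id = g$gene_id)
  expect_equal(canon$introns[, c("start", "end")],
               g$introns[, c("start", "end")])
  # paired-end bounds converge on the true transcript ends within read length
  expect_lte(bounds$tss, 75L)
  expect_gte(bounds$tes, nchar(g$seq) - 75L)
  cat2 <- classify_events(jx, aln, g)
  states <- split(
    mapply(sodsplice:::state_label, cat2$type, cat2$offset), cat2$intron
  )
  for (id in names(g$states)) {
    expect_setequal(states[[id]], g$states[[id]])
  }
  # with the true bounds the annotated model reproduces the fixture exactly
  m <- annotate_model(cat2, list(tss = 0L, tes = nchar(g$seq)), g$seq,
                      gene_id = g$gene_id)
  expect_equal(m$introns, g$introns)
  expect_equal(model_exons(m), model_exons(g))
})

test_that("raising the support floor never adds states", {
  g <- fx_mn1()
  reads <- simulate_read_pairs(
    g, config = sim_config(coverage = 100, error_rate = 0.005, seed = 13)
  )
  aln <- map_reads(reads, g$seq)
  lo <- classify_events(call_introns(aln, g$seq, min_support = 2L), aln, g,
                        min_support = 2L)
  hi <- classify_events(call_introns(aln, g$seq, min_support = 6L), aln, g,
                        min_support = 6L)
  key <- function(x) paste(x$intron, x$type, x$offset)
  expect_true(all(key(hi) %in% key(lo)))
})
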