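test_that("flattening cuts exonic bins at every splice boundary", {
  ## boundary set {1, 100, 151, 201, 300} enumerated by hand:
  ## bins [1,100], [151,200], [201,300]; junctions (100,201), (100,151)
  g <- gene_model("G1", "chr1", "+", list(
    transcript("t1", rbind(c(1, 100), c(201, 300))),
    transcript("t2", rbind(c(1, 100), c(151, 300)))
  ))
  u <- flatten_gene(g, read_length = 100)
  bins <- u[u$kind == "exonic_bin", ]
  jns <- u[u$kind == "junction", ]
  expect_equal(bins$start, c(1L, 151L, 201L))
  expect_equal(bins$end, c(100L, 200L, 300L))
  expect_equal(unname(cbind(jns$start, jns$end)),
               unname(rbind(c(100L, 151L), c(100L, 201L))))
  expect_equal(jns$effective_length, c(99, 99))
  ## membership: the A3SS extension bin belongs to t2 only
  expect_equal(u$members[[2]], "t2")
  expect_setequal(u$members[[1]], c("t1", "t2"))
})

test_that("single-transcript gene flattens to its exons plus one junction", {
  g <- gene_model("G1", "chr1", "+", list(
    transcript("t1", rbind(c(1, 100), c(201, 300)))
  ))
  u <- flatten_gene(g, read_length = 50)
  expect_equal(sum(u$kind == "exonic_bin"), 2L)
  expect_equal(sum(u$kind == "junction"), 1L)
  expect_equal(u$effective_length[u$kind == "junction"], 49)
  expect_error(flatten_gene(g, read_length = 1), "read_length")
})

test_that("exonic bins partition the exon union for generated genes", {
  genes <- synth_annotation(
    30, c(SE = 0.2, IR = 0.2, A3A5SS = 0.2, MXE = 0.2, complex = 0.2),
    seed = 11)
  for (g in genes) {
    u <- flatten_gene(g)
    bins <- u[u$kind == "exonic_bin", ]
    ## disjoint and sorted
    expect_true(all(diff(bins$start) > 0))
    expect_true(all(bins$start[-1] > bins$end[-nrow(bins)]))
    ## total bin length equals the exon-union length
    un <- dasbench:::gene_exon_union(g)
    expect_equal(sum(bins$end - bins$start + 1),
                 sum(un[, 2] - un[, 1] + 1))
    ## every bin interior is boundary-free: each bin lies inside one exon
    ## of every member transcript
    for (i in seq_len(nrow(bins))) {
      for (tid in bins$members[[i]]) {
        ex <- g$transcripts[[tid]]$exons
        expect_true(any(ex[, 1] <= bins$start[i] & ex[, 2] >= bins$end[i]))
      }
    }
  }
})

test_that("simple events are extracted and typed from constructed fixtures", {
  g <- se_gene()
  ev <- extract_events(g$transcripts[[1]], g$transcripts[[2]], "+", "Gse")
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "SE")
  expect_equal(ev[[1]]$region, c(201L, 300L))

  g <- ir_gene()
  ev <- extract_events(g$transcripts[[1]], g$transcripts[[2]], "+", "Gir")
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "IR")
  expect_equal(ev[[1]]$region, c(101L, 200L))

  ## identical structures: no events, not an error
  t1 <- transcript("a", rbind(c(1, 100), c(201, 300)))
  expect_length(extract_events(t1, t1, "+"), 0)
})

test_that("alternative splice-site events are strand-aware", {
  g <- a5ss_gene(strand = "+")
  ev <- extract_events(g$transcripts[[1]], g$transcripts[[2]], "+", "G")
  expect_length(ev, 1)
  expect_equal(ev[[1]]$type, "A5SS")  # donor-side difference on + strand
  ev_minus <- extract_events(g$transcripts[[1]], g$transcripts[[2]], "-", "G")
  expect_equal(ev_minus[[1]]$type, "A3SS")
})

test_that("strand flips swap donor/acceptor roles and coordinate mirroring preserves them", {
  mirror <- function(tr, around = 1000L) {
    ex <- tr$exons
    transcript(tr$transcript_id,
               cbind(around - ex[, 2], around - ex[, 1])[rev(seq_len(nrow(ex))), ,
                                                         drop = FALSE])
  }
  genes <- synth_annotation(
    20, c(SE = 0.25, IR = 0.25, A3A5SS = 0.25, MXE = 0.25), seed = 23)
  swap <- c(SE = "SE", IR = "IR", MXE = "MXE", A3SS = "A5SS", A5SS = "A3SS",
            complex = "complex")
  for (g in genes) {
    ev <- extract_events(g$transcripts[[1]], g$transcripts[[2]],
                         g$strand, g$gene_id)
    types <- vapply(ev, `[[`, character(1), "type")
    flip <- if (g$strand == "+") "-" else "+"

    ## same coordinates, opposite strand: donor and acceptor sides swap
    ev_f <- extract_events(g$transcripts[[1]], g$transcripts[[2]],
                           flip, g$gene_id)
    expect_equal(sort(unname(swap[types])),
                 sort(vapply(ev_f, `[[`, character(1), "type")))

    ## mirrored coordinates with the flipped strand describe the same
    ## molecule: event types are preserved
    m <- 10L + gene_span(g)[2]
    ev_m <- extract_events(mirror(g$transcripts[[1]], m),
                           mirror(g$transcripts[[2]], m),
                           flip, g$gene_id)
    expect_equal(sort(types), sort(vapply(ev_m, `[[`, character(1), "type")))
  }
})

test_that("event inclusion/exclusion units are disjoint and non-empty", {
  for (g in list(se_gene(), ir_gene(), a5ss_gene())) {
    evs <- gene_events(g)
    expect_length(evs, 1)
    e <- evs[[1]]
    expect_gt(length(e$inclusion_units), 0)
    expect_gt(length(e$exclusion_units), 0)
    expect_length(intersect(e$inclusion_units, e$exclusion_units), 0)
  }
  ## SE: inclusion = exon bin + 2 junctions; exclusion = skip junction
  e <- gene_events(se_gene())[[1]]
  expect_setequal(e$inclusion_units,
                  c("Gse:E:201-300", "Gse:J:100-201", "Gse:J:300-401"))
  expect_equal(e$exclusion_units, "Gse:J:100-401")
})

test_that("gene classification follows the event structure", {
  expect_equal(classify_gene(se_gene())$class, "SE")
  expect_equal(classify_gene(se_gene())$n_transcripts, 2L)
  expect_equal(classify_gene(ir_gene())$class, "IR")
  expect_equal(classify_gene(a5ss_gene())$class, "A3A5SS")

  ## one skipped exon AND one alternative boundary -> multi_event
  g <- gene_model("Gm", "chr1", "+", list(
    transcript("m.1", rbind(c(1, 100), c(201, 300), c(401, 500), c(601, 700))),
    transcript("m.2", rbind(c(1, 100), c(401, 530), c(601, 700)))
  ))
  expect_equal(classify_gene(g)$class, "multi_event")

  ## one transcript -> single_isoform; identical pair -> single_isoform
  g1 <- gene_model("Gs", "chr1", "+", list(
    transcript("s.1", rbind(c(1, 100)))))
  expect_equal(classify_gene(g1)$class, "single_isoform")
})

test_that("incomplete-annotation transform removes exactly the alt isoforms", {
  genes <- synth_annotation(20, c(SE = 0.5, IR = 0.5), seed = 3)
  params <- default_nb_params(names(genes), "Same", seed = 4)
  truth <- choose_true_as_genes(genes, params, 8, seed = 5)
  out <- make_incomplete_annotation(genes, truth)

  n_before <- sum(vapply(genes, n_transcripts, integer(1)))
  n_after <- sum(vapply(out, n_transcripts, integer(1)))
  expect_equal(n_before - n_after, 8L)
  expect_true(all(vapply(out, n_transcripts, integer(1)) >= 1L))
  ## true AS genes lost exactly their alternative transcript
  for (i in which(truth$is_true_as)) {
    gid <- truth$gene_id[i]
    expect_false(truth$alt_transcript_id[i] %in% names(out[[gid]]$transcripts))
  }
  ## non-AS genes are untouched (identical serialization)
  for (gid in truth$gene_id[!truth$is_true_as]) {
    expect_identical(out[[gid]], genes[[gid]])
  }
  ## idempotent on its own output
  expect_identical(make_incomplete_annotation(out, truth), out)
  ## strict mode raises the consistency error instead
  expect_error(make_incomplete_annotation(out, truth, strict = TRUE),
               "absent")
})

test_that("synthetic annotation realizes the requested classes deterministically", {
  genes <- synth_annotation(50, c(SE = 1.0), seed = 2)
  expect_length(genes, 50)
  expect_true(all(vapply(genes, function(g) classify_gene(g)$class,
                         character(1)) == "SE"))

  ## deterministic allocation: exact class counts, not sampling
  mix <- c(SE = 0.25, IR = 0.25, A3A5SS = 0.25, complex = 0.25)
  genes <- synth_annotation(400, mix, seed = 9)
  cls <- table(vapply(genes, function(g) classify_gene(g)$class, character(1)))
  expect_equal(unname(cls[c("SE", "IR", "A3A5SS", "complex")]),
               rep(100L, 4), ignore_attr = TRUE)

  ## same seed twice -> identical serialized annotation
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_annotation(synth_annotation(25, mix, seed = 31), f1, "GFF3")
  write_annotation(synth_annotation(25, mix, seed = 31), f2, "GFF3")
  expect_identical(readLines(f1), readLines(f2))

  expect_error(synth_annotation(10, c(SE = 0.5)), "sum to 1")
  expect_error(
    synth_annotation(10, c(SE = 1), length_params = list(exon = c(5, 8),
                                                         intron = c(50, 60),
                                                         gap = 100)),
    "infeasible")
})

test_that("GFF3 and GTF round-trip preserves gene models", {
  ## minimal hand-written GFF3: one gene, one mRNA, one exon [100,200]
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=g1.1;Parent=g1",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tParent=g1.1"
  ), f)
  genes <- parse_annotation(f, "GFF3")
  expect_length(genes, 1)
  expect_equal(genes$g1$transcripts[[1]]$exons,
               cbind(start = 100L, end = 200L))

  ## writer -> parser identity on generated annotation, both dialects
  genes <- synth_annotation(15, c(SE = 0.4, IR = 0.3, A3A5SS = 0.3), seed = 6)
  for (d in c("GFF3", "GTF")) {
    path <- tempfile(fileext = tolower(paste0(".", d)))
    write_annotation(genes, path, d)
    back <- parse_annotation(path, d)
    expect_identical(lapply(back, unclass), lapply(genes, unclass))
  }
})

test_that("malformed annotation records are reported with their line number", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t100\t200"  # truncated record on line 3
  ), f)
  expect_error(parse_annotation(f, "GFF3"), "line 3")

  f2 <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\texon\t100\t200\t.\t+\t.\tID=x"  # exon without parent
  ), f2)
  expect_error(parse_annotation(f2, "GFF3"), "parent")
})

test_that("annotation summary reports composition and longest gene", {
  mix <- c(SE = 0.2, IR = 0.4, A3A5SS = 0.2, single_isoform = 0.2)
  genes <- synth_annotation(50, mix, seed = 13)
  s <- annotation_summary(genes)
  expect_equal(s$n_genes, 50L)
  expect_equal(s$n_multi_isoform, 40L)
  expect_equal(s$n_two_tx_single_event, 40L)
  expect_equal(unname(s$partition), c(10L, 20L, 10L))
  expect_equal(s$longest_gene_nt,
               max(vapply(genes, function(g) diff(gene_span(g)) + 1L,
                          integer(1))))
})
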