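# A 3-sample simulated compendium shared by the table tests.
local_comp <- function(env = parent.frame(), atlas_mode = FALSE,
                       seed = 21) {
  dir <- withr::local_tempdir(.local_envir = env)
  samples <- list(
    list(name = "ctrl", mixture = c(g1.1 = 1), title = "Control leaf",
         controls = "ctrl"),
    list(name = "heat1", mixture = c(g1.1 = 0.5, g1.2 = 0.5),
         title = "Heat stress leaf 30 min", controls = "ctrl"),
    list(name = "heat2", mixture = c(g1.2 = 1), title = "Heat stress leaf 60 min",
         controls = "ctrl"))
  spec <- sim_spec(seed = seed, archetype = "skip", depth = 25,
                   samples = samples)
  cp <- make_compendium(spec, dir, atlas_mode = atlas_mode)
  cp
}

test_that("build_table yields one row per sample with scores for every variant", {
  cp <- local_comp()
  tb <- suppressMessages(build_table(cp$gene, cp$compendium, mode = "relative"))
  expect_length(tb$rows, 3L)
  df <- as.data.frame(tb)
  expect_true(all(c("rpb_g1.1", "rpb_g1.2") %in% names(df)))
  expect_true(all(df$status == "ok"))
  # control-equal sample has relative value 0
  expect_equal(df$rpkm_relative[df$sample == "ctrl"], 0)
  # determinism: rebuilt table is value-identical
  tb2 <- suppressMessages(build_table(cp$gene, cp$compendium, mode = "relative"))
  expect_equal(as.data.frame(tb2), df)
})

test_that("an unreadable BAM flags the row failed but the table survives", {
  cp <- local_comp()
  comp <- cp$compendium
  comp$samples$heat1$bam_url <- "/nonexistent/gone.bam"
  tb <- suppressMessages(build_table(cp$gene, comp))
  df <- as.data.frame(tb)
  expect_match(df$status[df$sample == "heat1"], "^failed: ")
  expect_true(is.na(df$rpkm_absolute[df$sample == "heat1"]))
  expect_equal(sum(df$status == "ok"), 2L)
  # failed rows sort last and export with their reason
  st <- sort_table(tb, "rpb", "desc")
  expect_equal(table_names(st)[3], "heat1")
  out <- withr::local_tempfile(fileext = ".csv")
  export_table(tb, "csv", out)
  expect_equal(nrow(utils::read.csv(out)), 3L)
})

test_that("sorting is stable, tie-broken by config order, undefined last", {
  t <- random_table(12, seed = 31)
  rpb <- c(0.2, 0.9, NaN, 0.9)
  for (i in 1:4) t$rows[[i]]$summary$rpb_by_variant["v1"] <- rpb[i]
  t$rows <- t$rows[1:4]
  st <- sort_table(t, "rpb", "desc")
  expect_equal(table_names(st), c("s002", "s004", "s001", "s003"))
  # asc reverses the defined block, undefined still last
  sa <- sort_table(t, "rpb", "asc")
  expect_equal(table_names(sa), c("s001", "s002", "s004", "s003"))
})

test_that("sorting 100 random rows matches an independent comparison sort", {
  t <- random_table(100, seed = 33)
  for (key in c("rpkm", "rpb")) {
    for (dir in c("desc", "asc")) {
      st <- sort_table(t, key, dir)
      v <- vapply(t$rows, function(r)
        if (key == "rpkm") r$summary$rpkm_absolute
        else r$summary$rpb_by_variant[["v1"]], numeric(1))
      cfg <- seq_along(v)
      val <- ifelse(is.nan(v), NA, v)
      # independent oracle: explicit rank construction
      key_order <- if (dir == "desc") -xtfrm(val) else xtfrm(val)
      oracle <- order(is.na(val), key_order, cfg)
      expect_equal(table_names(st), sprintf("s%03d", oracle))
      # permutation conservation
      expect_equal(sort(table_names(st)), sort(table_names(t)))
    }
  }
})

test_that("filtering is a case-insensitive substring match that commutes with sorting", {
  t <- random_table(60, seed = 35)
  f <- filter_table(t, "HEAT")
  expect_true(all(grepl("heat", vapply(f$rows, function(r) r$sample$title, ""))))
  expect_gt(length(f$rows), 0)
  expect_identical(filter_table(t, ""), t)
  # commutation with sort
  a <- sort_table(filter_table(t, "heat"), "rpb", "desc")
  b <- filter_table(sort_table(t, "rpb", "desc"), "heat")
  expect_equal(table_names(a), table_names(b))
  # filters commute with each other
  x <- filter_table(filter_table(t, "heat"), "leaf")
  y <- filter_table(filter_table(t, "leaf"), "heat")
  expect_equal(table_names(x), table_names(y))
})

test_that("exports round-trip at 6 significant digits in all three formats", {
  cp <- local_comp()
  tb <- suppressMessages(build_table(cp$gene, cp$compendium, mode = "relative"))
  df <- as.data.frame(tb)
  csv <- withr::local_tempfile(fileext = ".csv")
  export_table(tb, "csv", csv)
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), 3L)
  for (col in c("rpkm_absolute", "rpkm_relative", "rpb_g1.1", "rpb_g1.2")) {
    expect_equal(back[[col]], signif(df[[col]], 6), tolerance = 1e-6)
  }
  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_table(tb, "tsv", tsv)
  expect_equal(length(readLines(tsv)), 4L)  # header + 3 rows
  js <- withr::local_tempfile(fileext = ".json")
  export_table(tb, "json", js)
  parsed <- jsonlite::read_json(js)
  expect_length(parsed, 3L)
  need <- c("sample", "title", "sra_id", "reads_in_region", "rpkm_absolute",
            "rpkm_relative", "rpb_g1.1", "rpb_g1.2", "status")
  for (row in parsed) expect_true(all(need %in% names(row)))
})

test_that("undefined values export as empty fields (csv) and null (json)", {
  t <- random_table(3, seed = 40)
  t$rows[[2]]$summary$rpb_by_variant[] <- NaN
  csv <- withr::local_tempfile(fileext = ".csv")
  export_table(t, "csv", csv)
  back <- utils::read.csv(csv)
  expect_true(is.na(back$rpb_v1[2]))
  js <- withr::local_tempfile(fileext = ".json")
  export_table(t, "json", js)
  expect_null(jsonlite::read_json(js)[[2]]$rpb_v1)
})

test_that("efp_color interpolates the documented scales and clamps", {
  ab <- efp_scale("absolute", 10)
  expect_equal(efp_color(0, ab), "#FFFF00")
  expect_equal(efp_color(10, ab), "#FF0000")
  expect_equal(efp_color(99, ab), "#FF0000")            # clamped
  # midpoint equals the channel-wise average computed independently
  ch <- round((grDevices::col2rgb("#FFFF00")[, 1] +
                 grDevices::col2rgb("#FF0000")[, 1]) / 2)
  mid <- sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])
  expect_equal(efp_color(5, ab), mid)
  rel <- efp_scale("relative", 2)
  expect_equal(efp_color(0, rel), "#FFFF00")
  expect_equal(efp_color(-2, rel), "#0000FF")
  expect_equal(efp_color(2, rel), "#FF0000")
  expect_equal(efp_color(NA, rel), "#D3D3D3")
  expect_equal(efp_color(NaN, rel), "#D3D3D3")
  # monotone non-decreasing redness (falling green channel) in absolute mode
  greens <- sapply(seq(0, 12, by = 0.5), function(v)
    grDevices::col2rgb(efp_color(v, ab))["green", 1])
  expect_true(all(diff(greens) <= 0))
  expect_error(efp_scale("absolute", 0), "positive")
})

test_that("table_scale derives the ceiling from the table's values", {
  t <- random_table(10, seed = 44)
  sc <- table_scale(t)
  expect_equal(sc$mode, "absolute")
  expect_equal(sc$max, max(vapply(t$rows, function(r)
    r$summary$rpkm_absolute, numeric(1))))
})
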