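tinyScene <- function(seed = 12L, ...) {
  smallScene(frameSize = c(320, 180), bodySemiAxes = c(45, 18),
             pawLateralOffset = 40, pawCaudalOffset = 75,
             tsLeft = 26, itsLeft = 13, tsRight = 30, itsRight = 16,
             blobRadius = 4, seed = seed, ...)
}

test_that("frame streams honour stride and keep monotone frame indices", {
  out <- file.path(tempdir(), "stride.tif")
  renderVideo(tinyScene(), 10L, out)
  s1 <- readFrames(out, stride = 1L)
  expect_equal(s1@nFrames, 10L)
  expect_equal(s1@frameIndex, 0:9)
  s2 <- readFrames(out, stride = 2L)
  expect_equal(s2@nFrames, 5L)
  expect_equal(s2@frameIndex, c(0L, 2L, 4L, 6L, 8L))
  expect_identical(s2@getFrame(2L), s1@getFrame(3L))
  unlink(out)
})

test_that("PNG frame directories are a valid video source", {
  dirPath <- file.path(tempdir(), "framesdir")
  renderVideo(tinyScene(), 4L, dirPath)
  src <- readFrames(dirPath)
  expect_equal(src@nFrames, 4L)
  f <- src@getFrame(1L)
  expect_identical(dim(f), c(180L, 320L))
  expect_true(all(f >= 0 & f <= 1))
  unlink(dirPath, recursive = TRUE)
})

test_that("missing and unsupported files error per file", {
  expect_error(readFrames(file.path(tempdir(), "nope.tif")), "not found")
  bad <- file.path(tempdir(), "notavideo.xyz")
  writeLines("x", bad)
  expect_error(readFrames(bad), "unsupported")
  unlink(bad)
})

test_that("crop configs round-trip through YAML with defaults and overrides", {
  cfg <- setCropEntry(NULL, "vid1", c(0, 0, 100, 0, 100, 80, 0, 80),
                      operatedSide = "right")
  cfg$default <- list(full_frame = TRUE)
  path <- file.path(tempdir(), "crop.yaml")
  writeCropConfig(cfg, path)
  cfg2 <- readCropConfig(path)
  lk <- lookupCrop(cfg2, "vid1", "left")
  expect_equal(lk$roi, matrix(c(0, 0, 100, 0, 100, 80, 0, 80),
                              ncol = 2, byrow = TRUE))
  expect_identical(lk$operatedSide, "right")  # per-video override wins
  lkDef <- lookupCrop(cfg2, "otherVideo", "left")
  expect_null(lkDef$roi)
  expect_identical(lkDef$operatedSide, "left")
  # no entry and no default is an error
  cfg2$default <- NULL
  expect_error(lookupCrop(cfg2, "otherVideo", "left"), "no crop entry")
  unlink(path)
})

test_that("degenerate crop entries are rejected when looked up", {
  cfg <- structure(list(videos = list(
    bad = list(roi = c(0, 0, 5, 0, 10, 0, 15, 0)))), class = "cropConfig")
  expect_error(lookupCrop(cfg, "bad", "left"), "zero area")
})

resultFixture <- function() {
  r <- ssiRecords(c(0L, 3L, 7L), c(60, 61, 59.5), c(30, 30.5, 29),
                  c(80, 79, 80.5), c(40, 40.5, 39.5))
  s <- validateVideo(summarizeVideo(r, nFramesTotal = 10L))
  list(records = r, summary = s)
}

test_that("result export writes the pinned XLSX layout plus a CSV mirror", {
  fx <- resultFixture()
  outDir <- file.path(tempdir(), "OutputTest")
  files <- writeResults(fx$records, fx$summary, outDir, "video7")
  expect_true(all(file.exists(files)))
  # CSV mirror round-trips at 6 decimals
  csv <- read.csv(files["csv"])
  expect_identical(names(csv),
                   c("frame_index", "TSo", "ITSo", "TSc", "ITSc",
                     "TSF", "ITSF", "SSI", "outlier"))
  expect_equal(nrow(csv), 3L)
  for (col in c("TSo", "ITSo", "TSc", "ITSc", "TSF", "ITSF", "SSI"))
    expect_equal(csv[[col]], round(fx$records[[col]], 6), tolerance = 1e-9)
  expect_equal(csv$frame_index, fx$records$frame_index)
  # re-export is byte-identical (determinism contract)
  bytes1 <- readBin(files["csv"], "raw", file.size(files["csv"]))
  writeResults(fx$records, fx$summary, outDir, "video7")
  bytes2 <- readBin(files["csv"], "raw", file.size(files["csv"]))
  expect_identical(bytes1, bytes2)
  unlink(outDir, recursive = TRUE)
})

test_that("the XLSX workbook is a readable OOXML package with both sheets", {
  fx <- resultFixture()
  outDir <- file.path(tempdir(), "OutputXlsx")
  files <- writeResults(fx$records, fx$summary, outDir, "videoX")
  exDir <- file.path(tempdir(), "unz")
  unlink(exDir, recursive = TRUE)
  got <- utils::unzip(files["xlsx"], exdir = exDir)
  expect_true(any(grepl("workbook.xml$", got)))
  wb <- xml2::read_xml(file.path(exDir, "xl", "workbook.xml"))
  sheets <- xml2::xml_find_all(wb, "//*[local-name()='sheet']")
  expect_identical(xml2::xml_attr(sheets, "name"),
                   c("measurements", "summary"))
  sh1 <- xml2::read_xml(file.path(exDir, "xl", "worksheets", "sheet1.xml"))
  rows <- xml2::xml_find_all(sh1, "//*[local-name()='row']")
  expect_equal(length(rows), nrow(fx$records) + 1L)  # header + data
  # first data cell of the SSI column matches the record
  vals <- xml2::xml_text(xml2::xml_find_all(
    sh1, "//*[local-name()='row'][2]/*[local-name()='c']/*[local-name()='v']"))
  expect_equal(as.numeric(vals[8]), fx$records$SSI[1], tolerance = 1e-6)
  # summary sheet carries the QC reason codes
  sh2 <- xml2::read_xml(file.path(exDir, "xl", "worksheets", "sheet2.xml"))
  txt <- xml2::xml_text(sh2)
  expect_match(txt, "qc_reasons")
  expect_match(txt, "TOO_FEW_FRAMES")
  unlink(c(outDir, exDir), recursive = TRUE)
})

test_that("openpyxl (independent reader) agrees with the written workbook", {
  fx <- resultFixture()
  outDir <- file.path(tempdir(), "OutputPy")
  files <- writeResults(fx$records, fx$summary, outDir, "videoPy")
  script <- sprintf(
    "import openpyxl; wb = openpyxl.load_workbook(r'%s'); ws = wb['measurements']; print(ws.max_row, ws.cell(row=2, column=8).value)",
    files["xlsx"])
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = TRUE))
  ok <- is.null(attr(out, "status"))
  expect_true(ok)
  if (ok) {
    parts <- strsplit(tail(out, 1), " ")[[1]]
    expect_equal(as.integer(parts[1]), 4L)
    expect_equal(as.numeric(parts[2]), fx$records$SSI[1], tolerance = 1e-6)
  }
  unlink(outDir, recursive = TRUE)
})

test_that("the zip CRC implementation matches the known check value", {
  # classic CRC-32 test vector
  expect_equal(pawSSI:::crc32(charToRaw("123456789")), 0xCBF43926)
})
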