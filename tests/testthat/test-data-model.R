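test_that("bone ages are extracted from report text per the cohort rules", {
  # range -> mean in months, floored to years
  expect_identical(parse_bone_age("bone age is 13 to 14 years"), 13L)
  expect_identical(parse_bone_age("bone age 13-14 years"), 13L)
  expect_identical(parse_bone_age("skeletal age 13–14 years"), 13L)
  # skeletally mature and the 18-year cap
  expect_identical(parse_bone_age("the patient is skeletally mature"), 18L)
  expect_identical(parse_bone_age("bone age 19 years"), 18L)
  # single values, with and without months
  expect_identical(parse_bone_age("bone age 7 years"), 7L)
  expect_identical(parse_bone_age("bone age 9 years 11 months"), 9L)
  # below-cohort ages are rejected, not clipped
  expect_error(parse_bone_age("bone age 3 years"), class = "baa_out_of_cohort")
  # no keyword / no value / conflicting statements
  expect_error(parse_bone_age("normal examination"),
               class = "baa_unparseable_report")
  expect_error(parse_bone_age("bone age pending"),
               class = "baa_unparseable_report")
  expect_error(parse_bone_age("bone age 8 years, previously bone age 11 years"),
               class = "baa_unparseable_report")
})

test_that("parse_bone_age is idempotent on its own rendered output", {
  for (a in c(5L, 9L, 14L, 18L)) {
    expect_identical(parse_bone_age(sprintf("bone age %d years", a)), a)
  }
})

test_that("dataset splits are 70/15/15, deterministic and disjoint", {
  s <- split_dataset(1:100, seed = 3)
  expect_length(s$train_ids, 70)
  expect_length(s$validation_ids, 15)
  expect_length(s$test_ids, 15)
  # determinism / seed sensitivity
  expect_identical(split_dataset(1:20, seed = 1), split_dataset(1:20, seed = 1))
  expect_false(identical(split_dataset(1:20, seed = 1)$test_ids,
                         split_dataset(1:20, seed = 2)$test_ids))
  # proportions and partition across a range of N
  for (n in c(10, 37, 100, 1234, 10000)) {
    s <- split_dataset(seq_len(n), seed = 7)
    all_ids <- c(s$train_ids, s$validation_ids, s$test_ids)
    expect_length(all_ids, n)
    expect_length(unique(all_ids), n)
    expect_lte(abs(length(s$validation_ids) - round(0.15 * n)), 1)
    expect_lte(abs(length(s$test_ids) - round(0.15 * n)), 1)
  }
  expect_error(split_dataset(1:2, seed = 1), class = "baa_insufficient_data")
})

test_that("split files round-trip through JSON", {
  s <- split_dataset(sprintf("case%03d", 1:40), seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  write_split(s, f)
  expect_equal(read_split(f), s)
})

test_that("PNG radiographs round-trip at 8 and 16 bits", {
  ph <- generate_phantom(phantom_spec(height = 96, width = 80, seed = 5))
  f <- withr::local_tempfile(fileext = ".png")
  write_radiograph(ph$radiograph, f)
  back <- read_radiograph(f)
  expect_identical(back$pixels, ph$radiograph$pixels)
  expect_identical(back$bit_depth, 8L)

  ph16 <- generate_phantom(phantom_spec(height = 96, width = 80,
                                        bit_depth = 16, seed = 5))
  f16 <- withr::local_tempfile(fileext = ".png")
  write_radiograph(ph16$radiograph, f16)
  back16 <- read_radiograph(f16)
  expect_identical(back16$pixels, ph16$radiograph$pixels)
  expect_identical(back16$bit_depth, 16L)
})

test_that("our 16-bit PNG encoding is readable by an independent decoder", {
  ph16 <- generate_phantom(phantom_spec(height = 80, width = 72,
                                        bit_depth = 16, seed = 8))
  f16 <- withr::local_tempfile(fileext = ".png")
  write_radiograph(ph16$radiograph, f16)
  script <- sprintf(
    "import imageio.v3 as iio; import numpy as np; a = iio.imread(%s); print(a.dtype, a.shape, int(a.sum()))",
    shQuote(f16))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE)
  parts <- strsplit(out, " ")[[1]]
  expect_identical(parts[1], "uint16")
  expect_identical(as.numeric(parts[4]), sum(as.numeric(ph16$radiograph$pixels)))
})

test_that("color PNGs are rejected as radiographs", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(20 * 20 * 3), c(20, 20, 3)), f)
  expect_error(read_radiograph(f), class = "baa_format_error")
  expect_error(read_radiograph(withr::local_tempfile(fileext = ".xyz")),
               class = "baa_format_error")
})

test_that("monochrome DICOM written by pydicom is read back correctly", {
  ph <- generate_phantom(phantom_spec(height = 64, width = 64, seed = 6))
  csv <- withr::local_tempfile(fileext = ".csv")
  write.table(ph$radiograph$pixels, csv, row.names = FALSE, col.names = FALSE,
              sep = ",")
  d1 <- withr::local_tempfile(fileext = ".dcm")
  d2 <- withr::local_tempfile(fileext = ".dcm")
  script <- sprintf("
import numpy as np, pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian
px = np.loadtxt(%s, delimiter=',').astype(np.uint16)
for path, syntax, photo in [(%s, ExplicitVRLittleEndian, 'MONOCHROME2'),
                            (%s, ImplicitVRLittleEndian, 'MONOCHROME1')]:
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = pydicom.uid.SecondaryCaptureImageStorage
    meta.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()
    meta.TransferSyntaxUID = syntax
    ds = Dataset()
    ds.file_meta = meta
    ds.Rows, ds.Columns = px.shape
    ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = photo
    ds.BitsAllocated = 16
    ds.BitsStored = 16
    ds.HighBit = 15
    ds.PixelRepresentation = 0
    arr = px if photo == 'MONOCHROME2' else (65535 - px).astype(np.uint16)
    ds.PixelData = arr.tobytes()
    ds.save_as(path, enforce_file_format=True)
print('ok')
", shQuote(csv), shQuote(d1), shQuote(d2))
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = TRUE)
  expect_true(any(grepl("^ok$", out)))
  r1 <- read_radiograph(d1)
  expect_identical(r1$bit_depth, 16L)
  expect_identical(dim(r1$pixels), dim(ph$radiograph$pixels))
  expect_identical(r1$pixels, ph$radiograph$pixels)
  # MONOCHROME1 is inverted back to bright-is-high convention
  r2 <- read_radiograph(d2)
  expect_identical(r2$pixels, ph$radiograph$pixels)
})

test_that("manifests parse report text and drop unusable rows", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(
    id = c("a", "b", "c"), path = c("a.png", "b.png", "c.png"),
    sex = c("female", "male", "female"), chronological_age = c(8, 12, 2),
    report_text = c("bone age 8 years", "bone age 12 to 13 years",
                    "bone age 2 years")), f, row.names = FALSE)
  expect_warning(m <- read_manifest(f), class = "baa_dropped_rows")
  expect_identical(m$bone_age, c(8L, 12L))
  expect_identical(m$id, c("a", "b"))
})
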