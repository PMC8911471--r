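# rt_io: fraction bundles, the bundle archive, and the DICOM
# RTSTRUCT/RTDOSE adapters (cross-checked against pydicom as an
# independent implementation).

test_that("fraction_bundle validates structures, dose, and prescription", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5))
  m1 <- box_mask(g, 1:2, 1:2, 1:2, "A"); m2 <- box_mask(g, 3:4, 3:4, 3:4, "A")
  expect_error(fraction_bundle(g, list(m1, m2)), "unique")
  g2 <- voxel_grid(c(1, 0, 0), c(1, 1, 1), c(5, 5, 5))
  expect_error(fraction_bundle(g, list(structure_mask(g2, NULL, "B"))),
               "incompatible")
  b <- fraction_bundle(g, list(m1), patient_id = "P9")
  expect_output(print(b), "P9")
})

test_that("get_structure is case-insensitive and honours aliases", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(5, 5, 5))
  b <- fraction_bundle(g, list(box_mask(g, 1:2, 1:2, 1:2, "Bladder")))
  expect_equal(get_structure(b, "bladder")$name, "Bladder")
  expect_equal(get_structure(b, "Vessie",
                             aliases = list(Vessie = "bladder"))$name,
               "Bladder")
  expect_error(get_structure(b, "Bowel"), "available")
})

test_that("bundle archive round-trips losslessly (property, random bundles)", {
  set.seed(111)
  for (r in 1:20) {
    g <- random_grid(c(7, 6, 5))
    structures <- list()
    for (i in seq_len(sample(0:3, 1)))
      structures[[i]] <- random_mask(g, runif(1, 0, 1),
                                     name = paste0("S", i),
                                     role = sample(c("OAR", "TARGET", "DERIVED"), 1))
    dose <- if (runif(1) < 0.7)
      dose_grid(g, array(runif(prod(g$shape), 0, 80), dim = g$shape))
    rx <- if (runif(1) < 0.5) prescription_spec(5, 5)
    b <- fraction_bundle(g, structures, dose,
                         patient_id = sprintf("P%d", r), fraction_id = "F1",
                         observer_id = "O1", prescription = rx)
    p <- tempfile(fileext = ".aqb")
    write_bundle(b, p)
    b2 <- read_bundle(p)
    expect_equal(b2$patient_id, b$patient_id)
    expect_true(grids_compatible(b2$grid, b$grid))
    expect_equal(names(b2$structures), names(b$structures))
    for (nm in names(b$structures)) {
      expect_identical(b2$structures[[nm]]$occupancy,
                       b$structures[[nm]]$occupancy)
      expect_equal(b2$structures[[nm]]$role, b$structures[[nm]]$role)
    }
    if (is.null(dose)) expect_null(b2$dose)
    else expect_identical(b2$dose$values, dose$values)    # bit-exact
    if (is.null(rx)) expect_null(b2$prescription)
    else expect_equal(b2$prescription$total_gy, rx$total_gy)
    unlink(p)
  }
})

test_that("bundle reader rejects corrupt, truncated, and foreign files", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 1), c(6, 6, 4))
  b <- fraction_bundle(g, list(box_mask(g, 2:4, 2:4, 2:3, "A")),
                       dose_grid(g, array(1, g$shape)))
  p <- tempfile(fileext = ".aqb")
  write_bundle(b, p)
  raw <- readBin(p, "raw", file.info(p)$size)

  expect_error(read_bundle(tempfile()), "not found")
  pf <- tempfile(); writeBin(charToRaw("GIF89a junk"), pf)
  expect_error(read_bundle(pf), "magic")
  pt <- tempfile(); writeBin(raw[1:20], pt)
  expect_error(read_bundle(pt), "truncated|corrupt")
  pt2 <- tempfile(); writeBin(raw[1:(length(raw) - 10)], pt2)
  expect_error(read_bundle(pt2), "truncated|corrupt")
  # unknown schema version
  hlen <- sum(as.integer(raw[5:8]) * 256^(0:3))
  hdr <- rawToChar(raw[9:(8 + hlen)])
  hdr2 <- sub('"version":1', '"version":9', hdr, fixed = TRUE)
  expect_equal(nchar(hdr2), nchar(hdr))    # guard: substitution happened
  pv <- tempfile()
  writeBin(c(raw[1:8], charToRaw(hdr2), raw[(9 + hlen):length(raw)]), pv)
  expect_error(read_bundle(pv), "version")
  unlink(c(p, pf, pt, pt2, pv))
})

test_that("RTDOSE round-trips within 16-bit quantisation and pydicom agrees", {
  g <- voxel_grid(c(12.5, -30, 40), c(1.5, 2, 3), c(12, 10, 6))
  set.seed(121)
  vals <- array(runif(prod(g$shape), 0, 62), dim = g$shape)
  d <- dose_grid(g, vals)
  p <- tempfile(fileext = ".dcm")
  write_rtdose(d, p, patient_id = "PX")
  d2 <- read_rtdose(p, g)
  expect_lt(max(abs(d2$values - vals)), max(vals) / 65000 + 1e-12)

  # independent reader: pydicom must see the same geometry and doses
  py <- sprintf("
import pydicom, numpy as np, sys
ds = pydicom.dcmread(r'%s')
assert ds.Modality == 'RTDOSE' and ds.DoseUnits == 'GY'
arr = ds.pixel_array * ds.DoseGridScaling   # frames x rows x cols
print(arr.shape[2], arr.shape[1], arr.shape[0])
print('%%.6f' %% arr.max())
print(' '.join(str(float(x)) for x in ds.ImagePositionPatient))
", p)
  out <- system2("python3", c("-c", shQuote(py)), stdout = TRUE)
  expect_equal(scan(text = out[1], quiet = TRUE), g$shape)
  expect_equal(scan(text = out[2], quiet = TRUE), max(d2$values),
               tolerance = 1e-4)
  expect_equal(scan(text = out[3], quiet = TRUE), g$origin, tolerance = 1e-6)
  unlink(p)
})

test_that("read_rtdose refuses geometry mismatches, printing both geometries", {
  g <- voxel_grid(c(0, 0, 0), c(1.5, 1.5, 3), c(8, 8, 4))
  d <- dose_grid(g, array(10, g$shape))
  p <- tempfile(fileext = ".dcm")
  write_rtdose(d, p)
  shifted <- voxel_grid(c(0, 0, 1), c(1.5, 1.5, 3), c(8, 8, 4))
  expect_error(read_rtdose(p, shifted), "mismatch")
  err <- tryCatch(read_rtdose(p, shifted), error = conditionMessage)
  expect_match(err, "file:")
  expect_match(err, "grid:")
  unlink(p)
})

test_that("RTSTRUCT round-trips polygons exactly and pydicom agrees", {
  sets <- list(
    CTV = slice_polygon_set("CTV", list(
      list(z = 12, xy = rbind(c(1.25, 2.5), c(30, 2.5), c(30, 42.75), c(1.25, 40))),
      list(z = 15, xy = rbind(c(5, 5), c(25, 6), c(20, 30))))),
    Bladder = slice_polygon_set("Bladder", list(
      list(z = 12, xy = rbind(c(-10, -5), c(0, -5), c(0, 5), c(-10, 5))))))
  p <- tempfile(fileext = ".dcm")
  write_rtstruct(sets, p, patient_id = "PY")
  r <- read_rtstruct(p)
  expect_equal(names(r), c("CTV", "Bladder"))
  expect_equal(length(r$CTV$polygons), 2)
  for (i in 1:2) {
    expect_equal(r$CTV$polygons[[i]]$z, sets$CTV$polygons[[i]]$z)
    expect_equal(r$CTV$polygons[[i]]$xy, sets$CTV$polygons[[i]]$xy,
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
  py <- sprintf("
import pydicom
ds = pydicom.dcmread(r'%s')
assert ds.Modality == 'RTSTRUCT'
names = [r.ROIName for r in ds.StructureSetROISequence]
print('|'.join(names))
c0 = ds.ROIContourSequence[0].ContourSequence[0]
print(int(c0.NumberOfContourPoints))
print(' '.join(str(float(v)) for v in c0.ContourData[:6]))
", p)
  out <- system2("python3", c("-c", shQuote(py)), stdout = TRUE)
  expect_equal(out[1], "CTV|Bladder")
  expect_equal(as.integer(out[2]), 4)
  expect_equal(scan(text = out[3], quiet = TRUE),
               c(1.25, 2.5, 12, 30, 2.5, 12))
  unlink(p)
})

test_that("reader accepts implicit VR little endian written by pydicom", {
  p <- tempfile(fileext = ".dcm")
  py <- sprintf("
import pydicom
from pydicom.dataset import Dataset, FileDataset, FileMetaDataset
from pydicom.uid import ImplicitVRLittleEndian
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = '1.2.840.10008.5.1.4.1.1.481.3'
meta.MediaStorageSOPInstanceUID = '1.2.3.4'
meta.TransferSyntaxUID = ImplicitVRLittleEndian
ds = FileDataset(r'%s', {}, file_meta=meta, preamble=b'\\x00'*128)
ds.SOPClassUID = meta.MediaStorageSOPClassUID
ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
ds.Modality = 'RTSTRUCT'
ds.PatientName = 'IMP'
roi = Dataset(); roi.ROINumber = 1; roi.ROIName = 'Imp'
ds.StructureSetROISequence = [roi]
c = Dataset(); c.ContourGeometricType = 'CLOSED_PLANAR'
c.NumberOfContourPoints = 3
c.ContourData = ['0', '0', '5', '10', '0', '5', '10', '10', '5']
rc = Dataset(); rc.ReferencedROINumber = 1; rc.ContourSequence = [c]
ds.ROIContourSequence = [rc]
ds.save_as(r'%s', enforce_file_format=True)
", p, p)
  system2("python3", c("-c", shQuote(py)))
  r <- read_rtstruct(p)
  expect_equal(names(r), "Imp")
  expect_equal(r$Imp$polygons[[1]]$z, 5)
  expect_equal(r$Imp$polygons[[1]]$xy, rbind(c(0, 0), c(10, 0), c(10, 10)),
               ignore_attr = TRUE)
  unlink(p)
})

test_that("read_rtstruct and read_rtdose reject the wrong modality", {
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(5, 5, 3))
  p <- tempfile(fileext = ".dcm")
  write_rtdose(dose_grid(g, array(1, g$shape)), p)
  expect_error(read_rtstruct(p), "RTDOSE")
  sets <- list(A = slice_polygon_set("A", list(
    list(z = 0, xy = rbind(c(0, 0), c(1, 0), c(1, 1))))))
  p2 <- tempfile(fileext = ".dcm")
  write_rtstruct(sets, p2)
  expect_error(read_rtdose(p2, g), "RTSTRUCT")
  unlink(c(p, p2))
})

test_that("rasterized RTSTRUCT contours reproduce the source mask", {
  # mask -> contours (rectangles per slice) -> file -> read -> rasterize
  g <- voxel_grid(c(0, 0, 0), c(1, 1, 2), c(20, 20, 4))
  occ <- array(FALSE, g$shape); occ[5:14, 7:12, 2:3] <- TRUE
  m <- structure_mask(g, occ, "Box")
  # half-voxel-outset rectangle per slice so voxel centres fall inside
  polys <- lapply(2:3, function(k) list(
    z = axis_coords(g, 3)[k],
    xy = rbind(c(3.5, 5.5), c(13.6, 5.5), c(13.6, 11.6), c(3.5, 11.6))))
  p <- tempfile(fileext = ".dcm")
  write_rtstruct(list(Box = slice_polygon_set("Box", polys)), p)
  m2 <- rasterize(read_rtstruct(p)$Box, g)
  expect_identical(m2$occupancy, occ)
  unlink(p)
})
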