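# Example pipeline configuration for `gliaquant segment`.
# channel_map names the TIFF pages in order; pixel_size_um is the pixel
# side length. Stage parameters fall back to the published defaults when
# omitted.
channel_map: [DAPI, TMEM119, P2RY12, FTL, Iba1, Abeta, AF]
pixel_size_um: 0.5
nucleus:
  nu: 2
  mu: 3
soma:
  nu: 2
  mu: 3
cytoplasm:
  nu: 2
  mu: 2
min_soma_area_px: 50
min_nucleus_area_px: 30
vessel_min_area_px: 4000
process_attach_radius_px: 10
connectivity: 8
require_nucleus_overlap: true
plaque_method: threshold
plaque_min_area_px: 100
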