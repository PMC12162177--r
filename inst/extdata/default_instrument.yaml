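# Default instrument: 18-channel LED wavelength-scanning illuminator with a
# monochrome camera. Channel rows follow the LED data sheets: peak wavelength
# (nm), spectral half width / FWHM (nm), full viewing angle (deg).
led_array:
  ring_radius_mm: 15
  channels:
    - {wavelength: 405, half_width: 19, viewing_angle: 102}
    - {wavelength: 420, half_width: 16, viewing_angle: 26}
    - {wavelength: 450, half_width: 20, viewing_angle: 40}
    - {wavelength: 470, half_width: 25, viewing_angle: 80}
    - {wavelength: 505, half_width: 30, viewing_angle: 86}
    - {wavelength: 525, half_width: 30, viewing_angle: 18}
    - {wavelength: 555, half_width: 25, viewing_angle: 40}
    - {wavelength: 590, half_width: 13, viewing_angle: 64}
    - {wavelength: 610, half_width: 15, viewing_angle: 30}
    - {wavelength: 630, half_width: 15, viewing_angle: 60}
    - {wavelength: 660, half_width: 18, viewing_angle: 80}
    - {wavelength: 700, half_width: 21, viewing_angle: 80}
    - {wavelength: 770, half_width: 26, viewing_angle: 14}
    - {wavelength: 800, half_width: 29, viewing_angle: 88}
    - {wavelength: 830, half_width: 35, viewing_angle: 14}
    - {wavelength: 850, half_width: 40, viewing_angle: 26}
    - {wavelength: 890, half_width: 75, viewing_angle: 40}
    - {wavelength: 910, half_width: 47, viewing_angle: 30}
camera:
  rows: 720
  cols: 1280
  bit_depth: 10
  fps_max: 120
  angular_fov: 90
  dark_mean: 8
  dark_sigma: 1
  read_sigma: 2
  full_well_scale: 900
timing:
  pw_frames: 1
  dt_frames: 1
link:
  rate_mbps: 400
  interpretation: binary
geometry:
  working_distance_mm: 70
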