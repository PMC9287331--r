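# Station table schema

Delimited text (CSV by default), one row per weather station of long-term
monthly normals. `synthetic_stations_example.csv` in this directory is a
small synthetic example produced by `synth_station_table()` (it is not real
station data).

Required columns:

| column | unit | notes |
|---|---|---|
| `station_id` | text | unique identifier |
| `latitude` | decimal degrees | -90..90 |
| `longitude` | decimal degrees | -180..180 |
| `altitude` | m | -500..9000 |
| `tmin_01`..`tmin_12` | degC | monthly minimum temperature |
| `tmax_01`..`tmax_12` | degC | monthly maximum temperature |
| `rh_01`..`rh_12` | percent | monthly relative humidity, 0..100 |
| `wind_01`..`wind_12` | m/s | monthly wind speed at 2 m |
| `srad_01`..`srad_12` | MJ/m2/day | monthly solar radiation |
| `prec_01`..`prec_12` | mm | monthly precipitation total |
| `et0_01`..`et0_12` | mm | station-reported monthly reference ET total |

Rows failing range checks are quarantined with a reason, not silently
dropped. Tables carrying `sunshine_*` columns instead of radiation are
rejected: convert sunshine duration to solar radiation before ingestion.
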