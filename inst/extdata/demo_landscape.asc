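ncols 16
nrows 16
xllcorner 0
yllcorner 0
cellsize 30
NODATA_value -9999
1 1 1 1 1 2 2 2 -9999 -9999 -9999 -9999 4 4 4 4
1 1 1 1 1 2 2 2 2 -9999 -9999 -9999 4 4 4 4
1 1 1 1 1 1 1 1 2 -9999 -9999 -9999 4 4 4 4
1 1 1 1 1 1 1 1 4 4 4 4 4 4 4 4
1 1 3 1 1 1 1 4 4 4 4 4 4 4 4 4
1 2 3 1 1 1 1 1 4 4 4 4 4 4 3 3
1 2 3 1 1 1 1 1 1 4 4 4 4 4 4 3
1 3 3 3 3 3 1 1 4 4 4 4 4 4 4 3
3 3 3 3 3 3 3 3 4 4 4 4 4 4 4 4
3 3 3 3 3 3 3 3 4 4 4 4 -9999 4 4 4
3 3 3 3 3 3 3 3 3 4 4 4 -9999 -9999 -9999 4
3 3 3 3 3 3 3 3 4 4 1 -9999 -9999 -9999 -9999 -9999
3 3 3 3 3 3 3 3 3 1 1 -9999 -9999 -9999 4 -9999
3 3 3 3 3 3 3 3 3 1 1 1 1 -9999 4 3
3 3 3 3 3 3 3 2 3 1 1 1 1 1 3 3
3 3 3 3 3 2 2 2 2 3 1 1 1 1 3 3
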