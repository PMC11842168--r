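{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"role":"lake","name":"Achonachie","approximate":true,"area_km2":0.6899988031},"geometry":{"type":"Polygon","coordinates":[[[869.94,0],[863.42,10.6],[855.5,21.04],[846.4,31.31],[836.31,41.39],[825.43,51.31],[813.89,61.06],[801.8,70.67],[789.23,80.14],[776.21,89.49],[762.71,98.73],[748.69,107.86],[734.05,116.88],[718.68,125.78],[702.47,134.52],[685.29,143.09],[667.01,151.44],[647.53,159.52],[626.77,167.28],[604.67,174.67],[581.23,181.63],[556.46,188.12],[530.43,194.08],[503.25,199.49],[475.04,204.32],[445.97,208.58],[416.22,212.26],[385.99,215.38],[355.45,218],[324.79,220.17],[294.18,221.94],[263.74,223.41],[233.57,224.64],[203.73,225.74],[174.22,226.78],[145.03,227.84],[116.07,229],[87.23,230.31],[58.38,231.82],[29.36,233.53],[0,235.47],[-29.87,237.6],[-60.41,239.88],[-91.75,242.25],[-123.99,244.64],[-157.19,246.95],[-191.36,249.08],[-226.44,250.91],[-262.35,252.32],[-298.92,253.21],[-335.96,253.46],[-373.22,252.99],[-410.41,251.71],[-447.24,249.56],[-483.38,246.5],[-518.51,242.5],[-552.33,237.57],[-584.56,231.72],[-614.95,225],[-643.3,217.47],[-669.45,209.2],[-693.31,200.28],[-714.85,190.79],[-734.07,180.84],[-751.05,170.52],[-765.89,159.92],[-778.75,149.13],[-789.81,138.22],[-799.25,127.26],[-807.28,116.3],[-814.08,105.38],[-819.82,94.52],[-824.66,83.73],[-828.71,73.04],[-832.04,62.42],[-834.69,51.88],[-836.64,41.41],[-837.84,30.99],[-838.23,20.62],[-837.68,10.29],[-836.07,0],[-833.27,-10.23],[-829.13,-20.39],[-823.53,-30.46],[-816.36,-40.41],[-807.55,-50.2],[-797.06,-59.8],[-784.88,-69.17],[-771.05,-78.29],[-755.66,-87.12],[-738.83,-95.64],[-720.71,-103.83],[-701.48,-111.69],[-681.34,-119.24],[-660.5,-126.49],[-639.17,-133.46],[-617.55,-140.21],[-595.79,-146.78],[-574.05,-153.21],[-552.42,-159.58],[-530.96,-165.93],[-509.7,-172.31],[-488.59,-178.77],[-467.56,-185.34],[-446.5,-192.05],[-425.26,-198.89],[-403.68,-205.86],[-381.56,-212.92],[-358.74,-220.02],[-335.03,-227.11],[-310.29,-234.1],[-284.39,-240.89],[-257.24,-247.41],[-228.8,-253.52],[-199.09,-259.14],[-168.14,-264.16],[-136.08,-268.49],[-103.03,-272.04],[-69.19,-274.74],[-34.77,-276.56],[-0,-277.46],[34.88,-277.44],[69.64,-276.51],[104.04,-274.7],[137.9,-272.08],[171.03,-268.7],[203.32,-264.66],[234.69,-260.04],[265.09,-254.95],[294.53,-249.49],[323.07,-243.74],[350.8,-237.79],[377.83,-231.73],[404.32,-225.61],[430.4,-219.48],[456.22,-213.37],[481.93,-207.29],[507.64,-201.23],[533.42,-195.17],[559.32,-189.08],[585.32,-182.91],[611.39,-176.61],[637.4,-170.12],[663.22,-163.39],[688.65,-156.35],[713.46,-148.98],[737.41,-141.21],[760.22,-133.04],[781.62,-124.46],[801.36,-115.45],[819.19,-106.04],[834.91,-96.25],[848.34,-86.14],[859.37,-75.74],[867.91,-65.11],[873.97,-54.33],[877.58,-43.44],[878.83,-32.51],[877.85,-21.59],[874.82,-10.74],[869.94,0]]]}},{"type":"Feature","properties":{"role":"start","initial_bearing":90.0000128493541},"geometry":{"type":"Point","coordinates":[-836.07,0]}},{"type":"Feature","properties":{"role":"capture_center","radius":10.2763495250838,"exposed_perimeter":31},"geometry":{"type":"Point","coordinates":[869.94,0]}}]}
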