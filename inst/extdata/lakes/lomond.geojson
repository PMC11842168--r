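{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"role":"lake","name":"Lomond","approximate":true,"area_km2":70.9999964701},"geometry":{"type":"Polygon","coordinates":[[[0,8753.86],[-100.1,8662.54],[-198.28,8565.99],[-294.73,8466.55],[-389.72,8366.01],[-483.57,8265.58],[-576.6,8165.83],[-669.13,8066.74],[-761.43,7967.7],[-853.68,7867.64],[-945.99,7765.03],[-1038.36,7658.1],[-1130.67,7544.84],[-1222.71,7423.25],[-1314.16,7291.35],[-1404.62,7147.36],[-1493.64,6989.78],[-1580.71,6817.43],[-1665.35,6629.57],[-1747.06,6425.86],[-1825.41,6206.4],[-1900.04,5971.7],[-1970.68,5722.61],[-2037.15,5460.26],[-2099.39,5186.02],[-2157.46,4901.34],[-2211.51,4607.73],[-2261.77,4306.62],[-2308.55,3999.3],[-2352.2,3686.89],[-2393.07,3370.23],[-2431.51,3049.91],[-2467.8,2726.25],[-2502.17,2399.32],[-2534.71,2069],[-2565.43,1735],[-2594.18,1396.99],[-2620.7,1054.61],[-2644.58,707.65],[-2665.3,356.05],[-2682.23,0],[-2694.7,-359.98],[-2701.97,-723.01],[-2703.33,-1087.86],[-2698.08,-1452.93],[-2685.61,-1816.28],[-2665.42,-2175.7],[-2637.17,-2528.78],[-2600.68,-2873.04],[-2555.94,-3205.99],[-2503.17,-3525.28],[-2442.76,-3828.84],[-2375.3,-4114.94],[-2301.55,-4382.36],[-2222.4,-4630.41],[-2138.83,-4859.02],[-2051.92,-5068.74],[-1962.74,-5260.8],[-1872.33,-5437],[-1781.67,-5599.67],[-1691.64,-5751.57],[-1602.94,-5895.78],[-1516.13,-6035.54],[-1431.54,-6174.08],[-1349.34,-6314.48],[-1269.44,-6459.51],[-1191.62,-6611.46],[-1115.44,-6772.01],[-1040.35,-6942.15],[-965.68,-7122.08],[-890.71,-7311.2],[-814.67,-7508.07],[-736.85,-7710.48],[-656.59,-7915.51],[-573.34,-8119.67],[-486.69,-8318.99],[-396.39,-8509.24],[-302.37,-8686.05],[-204.74,-8845.14],[-103.8,-8982.48],[-0,-9094.45],[106.06,-9178.01],[213.67,-9230.82],[322.05,-9251.31],[430.37,-9238.75],[537.84,-9193.26],[643.68,-9115.8],[747.22,-9008.06],[847.89,-8872.41],[945.28,-8711.77],[1039.12,-8529.42],[1129.31,-8328.88],[1215.93,-8113.72],[1299.16,-7887.39],[1379.36,-7653.11],[1456.96,-7413.66],[1532.44,-7171.34],[1606.32,-6927.86],[1679.09,-6684.29],[1751.2,-6441.09],[1822.97,-6198.09],[1894.6,-5954.59],[1966.14,-5709.43],[2037.47,-5461.13],[2108.29,-5207.98],[2178.1,-4948.22],[2246.27,-4680.14],[2312.01,-4402.28],[2374.45,-4113.46],[2432.62,-3812.95],[2485.57,-3500.49],[2532.34,-3176.39],[2572.08,-2841.44],[2604.02,-2496.99],[2627.58,-2144.81],[2642.38,-1787.05],[2648.23,-1426.09],[2645.21,-1064.48],[2633.6,-704.71],[2613.93,-349.19],[2586.95,-0],[2553.57,341.12],[2514.85,672.94],[2471.94,994.75],[2426.04,1306.44],[2378.34,1608.48],[2329.97,1901.88],[2281.94,2188.15],[2235.12,2469.19],[2190.17,2747.19],[2147.54,3024.43],[2107.44,3303.24],[2069.84,3585.76],[2034.46,3873.8],[2000.83,4168.76],[1968.25,4471.49],[1935.91,4782.16],[1902.85,5100.29],[1868.08,5424.66],[1830.57,5753.36],[1789.36,6083.84],[1743.56,6412.99],[1692.4,6737.26],[1635.29,7052.82],[1571.83,7355.67],[1501.81,7641.87],[1425.24,7907.66],[1342.36,8149.63],[1253.56,8364.86],[1159.44,8551.08],[1060.72,8706.7],[958.21,8830.93],[852.79,8923.73],[745.38,8985.88],[636.84,9018.88],[527.99,9024.86],[419.56,9006.49],[312.15,8966.85],[206.23,8909.26],[102.12,8837.15],[0,8753.86]]]}},{"type":"Feature","properties":{"role":"start","initial_bearing":330.004783161742},"geometry":{"type":"Point","coordinates":[2374.45,-4113.46]}},{"type":"Feature","properties":{"role":"capture_center","radius":64.4317373062138,"exposed_perimeter":200},"geometry":{"type":"Point","coordinates":[-2375.3,-4114.94]}}]}
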