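{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"role":"lake","name":"Bassenthwaite","approximate":true,"area_km2":5.09999879015},"geometry":{"type":"Polygon","coordinates":[[[0,2379.57],[-33.54,2390.43],[-67.26,2393.07],[-100.91,2387.21],[-134.22,2372.73],[-166.93,2349.73],[-198.79,2318.49],[-229.6,2279.45],[-259.15,2233.23],[-287.31,2180.59],[-313.97,2122.37],[-339.09,2059.49],[-362.66,1992.91],[-384.73,1923.58],[-405.41,1852.39],[-424.81,1780.18],[-443.11,1707.67],[-460.47,1635.47],[-477.08,1564.04],[-493.13,1493.69],[-508.78,1424.59],[-524.19,1356.76],[-539.46,1290.09],[-554.68,1224.37],[-569.87,1159.3],[-585.03,1094.53],[-600.09,1029.66],[-614.97,964.31],[-629.52,898.12],[-643.6,830.77],[-657.01,762],[-669.58,691.66],[-681.12,619.67],[-691.45,546.03],[-700.42,470.84],[-707.9,394.27],[-713.81,316.56],[-718.11,237.98],[-720.77,158.83],[-721.86,79.41],[-721.44,0],[-719.64,-79.17],[-716.59,-157.91],[-712.46,-236.11],[-707.44,-313.73],[-701.68,-390.8],[-695.35,-467.43],[-688.61,-543.78],[-681.56,-620.07],[-674.29,-696.52],[-666.82,-773.38],[-659.16,-850.86],[-651.26,-929.13],[-643.02,-1008.3],[-634.32,-1088.39],[-624.99,-1169.29],[-614.85,-1250.8],[-603.71,-1332.6],[-591.38,-1414.25],[-577.67,-1495.17],[-562.41,-1574.74],[-545.46,-1652.21],[-526.73,-1726.83],[-506.17,-1797.8],[-483.76,-1864.35],[-459.55,-1925.76],[-433.64,-1981.37],[-406.15,-2030.66],[-377.27,-2073.2],[-347.2,-2108.77],[-316.17,-2137.26],[-284.43,-2158.76],[-252.22,-2173.52],[-219.78,-2181.95],[-187.31,-2184.59],[-155.02,-2182.09],[-123.04,-2175.2],[-91.5,-2164.71],[-60.47,-2151.42],[-29.97,-2136.11],[-0,-2119.49],[29.5,-2102.19],[58.6,-2084.73],[87.39,-2067.46],[115.99,-2050.6],[144.51,-2034.21],[173.04,-2018.16],[201.67,-2002.21],[230.46,-1985.95],[259.41,-1968.88],[288.53,-1950.42],[317.75,-1929.93],[346.98,-1906.75],[376.07,-1880.26],[404.86,-1849.87],[433.14,-1815.09],[460.71,-1775.52],[487.33,-1730.9],[512.78,-1681.1],[536.85,-1626.14],[559.35,-1566.18],[580.12,-1501.51],[599.03,-1432.55],[616.03,-1359.79],[631.08,-1283.82],[644.21,-1205.26],[655.5,-1124.74],[665.06,-1042.86],[673.05,-960.22],[679.65,-877.31],[685.08,-794.55],[689.54,-712.28],[693.26,-630.71],[696.43,-549.95],[699.22,-470.03],[701.78,-390.86],[704.22,-312.31],[706.6,-234.17],[708.91,-156.22],[711.14,-78.23],[713.2,-0],[714.96,78.65],[716.26,157.84],[716.94,237.6],[716.8,317.88],[715.63,398.57],[713.25,479.46],[709.48,560.26],[704.17,640.64],[697.22,720.21],[688.54,798.57],[678.11,875.32],[665.95,950.09],[652.11,1022.56],[636.7,1092.48],[619.86,1159.69],[601.73,1224.11],[582.51,1285.79],[562.37,1344.87],[541.51,1401.58],[520.09,1456.24],[498.26,1509.25],[476.16,1561.02],[453.85,1611.99],[431.41,1662.59],[408.83,1713.19],[386.08,1764.09],[363.11,1815.49],[339.83,1867.45],[316.11,1919.92],[291.83,1972.68],[266.86,2025.36],[241.07,2077.45],[214.37,2128.31],[186.68,2177.17],[157.94,2223.19],[128.15,2265.49],[97.36,2303.14],[65.64,2335.24],[33.13,2360.97],[0,2379.57]]]}},{"type":"Feature","properties":{"role":"start","initial_bearing":89.9999801453431},"geometry":{"type":"Point","coordinates":[-721.44,0]}},{"type":"Feature","properties":{"role":"capture_center","radius":23.2658939874724,"exposed_perimeter":73},"geometry":{"type":"Point","coordinates":[713.2,0]}}]}
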